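Package: repomics
Title: Bacterial Replication Rates and Dual-Regression Multi-Omic
    Associations for Weight-Loss Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates contig-level bacterial replication rates from
    metagenome coverage profiles (iRep-style sorted log2-coverage slope on
    binned, sliding-window-smoothed depth) and runs a dual-regression
    association framework that separates baseline-BMI associations from
    weight-loss associations across multi-omic feature types (continuous
    log-scale analytes, ordinal diet frequencies, and sequencing counts
    with median-of-ratios "poscounts" normalization and negative-binomial
    regression). Includes cohort selection by relative weight change,
    rarefaction-based gene richness, Benjamini-Hochberg FDR control, and a
    synthetic-data generator with known ground truth for coverage
    gradients and cohort effect structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicAlignments,
    MASS,
    Rsamtools,
    limma,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
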