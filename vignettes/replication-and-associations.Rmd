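---
title: "Replication rates and dual-regression associations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication rates and dual-regression associations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repomics)
```

# Scope

`repomics` implements the two bespoke computations of a weight-loss
microbiome analysis — contig-level bacterial replication-rate inference from
metagenome coverage profiles, and a dual-regression framework that separates
baseline-BMI associations from weight-loss associations across multi-omic
feature types — together with the cohort-selection rules, the feature
preparation steps those analyses need, and a synthetic-data generator with
known ground truth. Everything upstream of these steps (read QC, assembly,
alignment, ORF calling, annotation, 16S processing) is out of scope: the
package consumes their tabular outputs.

# Cohort selection

The phenotype is the *relative weight change rate*

$$ r = 100 \cdot \frac{W_{\text{follow-up}} - W_{\text{baseline}}}
  {W_{\text{baseline}} \cdot m} \;\; [\%/\text{month}], $$

with $m$ the months between measurements. Subjects with $r < -1$ form the
weight-loss group; subjects with $0 \le r < 0.1$ form the no-weight-loss
group; subjects in between stay unassigned; subjects whose recorded weight
series has exactly zero variance are excluded outright, because repeated
identical values indicate a stale self-report rather than a stable weight.

Two conventions here were genuinely open and are package decisions:

* the rate is expressed **in percent of baseline weight** (dividing by the
  baseline), because the grouping criteria are phrased in percent of body
  weight; an absolute kg/month variant would order subjects differently
  when baseline weights differ.
* the stability bound 0.1 %, like the loss bound 1 %, is interpreted **per
  month** and bounded below by zero (no loss at all); both thresholds are
  arguments of `assign_group()`.

# Replication-rate inference

Actively replicating bacterial populations carry more genome copies near the
replication origin than near the terminus, so sequencing coverage along the
genome decays from origin to terminus. The peak-to-trough coverage ratio
(PTR) is a dimensionless growth index: 1 for a non-replicating population,
2 or higher for fast growers.

The estimator works on assembled contigs, where origin and terminus
positions are unknown, exploiting the fact that for an exponential
(log2-linear) coverage gradient the *sorted* coverage profile is log2-linear
in rank regardless of where the contig sits on the genome:

1. per-base depth is averaged in 100-bp bins; a trailing partial bin is
   dropped rather than padded, which would otherwise bias the low end of
   the sorted profile;
2. bins are smoothed with a 50-bin (5,000-bp) centered sliding-window mean,
   truncated at the contig ends;
3. only contigs of at least 11,000 bp with at least 2x mean raw-bin
   coverage are estimated (both thresholds inclusive, both configurable);
   the filter runs on *unsmoothed* bins so that smoothing cannot lift a
   contig over the coverage bar;
4. smoothed bins are sorted ascending, 5 % of bins are trimmed from each
   tail, values are log2-transformed (non-positive bins dropped and
   counted), and an ordinary least-squares line is fitted against the
   sorted rank rescaled to $[0,1]$ over the *pre-trim* range;
5. the replication rate is $2^{\hat\beta}$, the fitted coverage ratio
   across the sorted profile, reported per contig without extrapolating to
   a whole-genome PTR — origin/terminus positions are not identifiable from
   a contig, so the local gradient is the honest quantity.

Degenerate inputs are handled explicitly: constant coverage gives rate
exactly 1 (with undefined $R^2$, flagged), all-zero coverage or fewer than
10 usable bins refuses the estimate with a machine-readable reason, and the
optional `min_r2` quality gate is off by default (the fit quality is always
reported).

Under the synthetic generator's conditions — exponential gradient, Poisson
noise, 20x mean depth, 25-kb single-replichore contigs — the full chain
(bin, smooth, sort, trim, fit) recovers true PTRs of 1–3 with median error
below 0.05; the residual bias comes from edge truncation in the smoother
and is well inside the ±0.15 band the tests enforce. Scale invariance
(coverage times any constant leaves the rate unchanged) and monotonicity in
the true gradient hold by construction and are tested.

Taxon summaries are unweighted means of contig rates per sample and phylum;
contigs without a phylum classification are pooled under `NA` rather than
silently dropped, since unclassified contigs are the majority in shallow
assemblies and carry real signal. Group differences are tested with
`lm(mean_rate ~ group + age + baseline_bmi)` on per-sample means — for a
binary group this t test is the covariate-adjusted ANOVA. Covariates that
are constant within a scope are dropped (with a message) instead of
aborting the fit, which also makes the estimator reduce exactly to the
pooled two-sample t when no covariate varies. A per-contig mode (every
contig an observation) exists implicitly by passing contig-level tables,
but per-sample means are the default unit of inference because contigs
within a sample are not independent.

# Feature preparation

* **Metabolites** are median-scaled within batch over the study samples
  (making the within-batch median exactly 1), divided by the batch's
  QC-sample mean per metabolite ("average" read as the arithmetic mean),
  imputed to the metabolite's minimum observed normalized value, and
  log-transformed; QC samples are removed from the output.
* **Proteins** keep features with fewer than 5 % missing values, impute the
  rest to the feature minimum, and log-transform.
* **SRM panels** are reduced to within-subject change scores
  $\log(\text{follow-up}) - \log(\text{baseline})$ of light/heavy ratios.
* Natural logs are used throughout ("log-transformed" does not pin a base);
  the base is an argument, and every downstream t statistic is
  base-invariant.
* **Gene clusters** sum ORF counts by annotation term; unannotated ORFs are
  pooled under a reserved `unannotated` term that counts toward library
  size but is excluded from cluster-level analyses.
* **Size factors** use the zero-tolerant median-of-ratios ("poscounts")
  definition: per feature a reference $g_i = \exp\!\big(\tfrac{1}{n}
  \sum_{j: c_{ij}>0} \log c_{ij}\big)$, per sample the median of
  $c_{ij}/g_i$ over features positive in that sample, then a geometric-mean
  rescaling to 1 — the centering fixes the scale the method otherwise
  leaves free, making results reproducible across runs.
* **Rarefied richness** subsamples each sample's assigned-cluster counts
  without replacement to a fixed depth (default 100,000 reads) in a single
  seeded draw and counts clusters still observed; samples below the depth
  are excluded with a warning, not an error. An optional `repeats` argument
  averages several draws, but the single seeded draw is the default to
  match the single-downsampling design being emulated.

# The dual-regression framework

Every feature is fitted twice:

* **weight-loss model** — target: group indicator; covariates: baseline
  BMI, age, sex;
* **BMI model** — target: baseline BMI; covariates: age, sex (no group
  term).

Correcting the weight-loss model for baseline BMI is the point of the
design: subjects with high baseline BMI lose more weight on follow-up
(regression to the mean), so an unadjusted weight-loss association could be
a BMI association in disguise. No interaction terms are fitted — with a
25-sample subcohort, sex-by-group cells would be estimated from fewer than
six subjects.

Continuous (log-scale) and ordinal diet features use per-feature OLS with
*no* empirical-Bayes variance moderation; t = coefficient / standard error
with the residual-degrees-of-freedom t reference. Count features use
per-feature negative-binomial log-link regression with an offset of log
size factor; the dispersion is estimated per feature by maximum likelihood
with a method-of-moments fallback on non-convergence, and the Wald
pseudo-t uses a normal reference. Forgoing dispersion shrinkage across
features is a deliberate simplification of the borrowed-strength machinery
in dedicated count packages: the inferential contract (NB regression, Wald
statistic, BH correction) is preserved and fully specified, and the null
calibration of the resulting p values is enforced by simulation tests
rather than assumed.

P values are BH-adjusted **within each data type and model**, and each
feature is classified at FDR threshold `alpha` (default 0.05, the value
stated for gene clusters; configurable per type since other types'
thresholds are not pinned): `bmi_only`, `wl_only`, `both`, or `neither`.
Zero-variance and non-converged features are flagged and classified
`neither` rather than dropped, so output rows always match input features.
The Pearson correlation between the two t vectors (the biplot summary
statistic) is attached to every association table.

Sex is coded 0/1 against a configurable reference level (t magnitudes are
unaffected by the choice). Two-sided tests throughout.

# The synthetic-data generator

The generator defines the conditions under which the pipeline's guarantees
are demonstrated:

* **Coverage**: expected depth $\propto \text{PTR}^{1-x}$ with $x$ the
  circular distance from the origin divided by half the genome — the
  exponential form is the regime in which the sorted-slope estimator is
  consistent, matching the replication-biology model behind PTR inference.
  Poisson per-base noise; mean depth 20x by default (shallow-shotgun
  territory); genomes partitioned left-to-right into contigs.
* **Cohort**: 105 subjects by default with 48/105 in the weight-loss group
  (the study design being emulated); baseline BMI $\mathcal N(29, 5^2)$ and
  age $\mathcal N(48, 12^2)$, a plausible mostly-overweight middle-aged
  wellness cohort; sex Bernoulli(0.5). Weight trajectories are drawn
  consistently with the group label, so the cohort-selection rules
  re-derive the simulated groups exactly — an end-to-end consistency check.
* **Features**: continuous features are Gaussian on the log scale with
  linear BMI/group/sex effects; counts are negative binomial with mean
  (library-size factor) × exp(linear predictor), exercising the
  size-factor path jointly with the regression; ordinal diet scores
  discretize a latent Gaussian with the same predictor into nine
  equal-quantile bins. BMI and age enter centered at their simulation
  means so recovered coefficients equal the specified betas. Truth tables
  list every nonzero effect, sufficient to score any downstream
  classification.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: compositionality and taxon correlation structure in
count tables, batch effects beyond the modeled median/QC scaling,
non-exponential coverage gradients (GC bias, strain mixtures), repeated
measures, and missingness that is informative rather than random.

## A note on normalization and global effects

Median-of-ratios size factors assume most features are not differential.
If *every* count feature is doubled in one group, the doubling is absorbed
into the size factors and group coefficients shrink toward zero — a
property of the normalization, not an estimation error. The power
demonstrations therefore embed affected count features (10 %) in a
mostly-null background, the regime the real analysis occupies (tens of
significant clusters among ~3,000).

# Problem sizes and numerical choices

The validation suite runs at deliberately modest scale, chosen as the
smallest sizes at which the statistical claims are meaningful: 200
replicates per PTR level for rate recovery (25-kb contigs, 20x), 200
replicates for group-test power and null calibration (n = 25 samples,
matching the metagenomic subcohort), 20 seeds × 1,000 features for NB null
calibration, 100 + 900 features for NB power, 200 features for dual-model
orthogonality (n = 105), and 100 replicates for richness-slope recovery
(n = 105, slope −19 clusters per BMI unit, noise SD 100). Fixed seeds make
every number reproducible; `scripts/acceptance.R` recomputes all of them
from scratch for any seed.

Ties and degenerate cases are resolved explicitly rather than left to
chance: inclusive eligibility thresholds, trailing-bin dropping, symmetric
trim via `floor(trim_fraction * n)` per tail, constant profiles returning
rate 1 with a flag, refusal reasons as machine-readable strings, and BH
passing NA through untouched (flagged features are excluded from the
adjusted set by the callers).

# Known limitations

* Contig-level rates are local gradients, not whole-genome PTRs; comparing
  them across contigs of very different lengths conflates gradient span
  with growth.
* Per-feature NB dispersion estimates are noisy at n = 25; the Wald normal
  reference is anti-conservative for very low counts. The null-calibration
  test bounds the practical consequence but does not remove it.
* The ordinal diet models treat 0–8 scores as numeric responses (as in the
  analysis being emulated); a proportional-odds model would be the
  principled alternative.
* Single-draw rarefaction adds sampling noise to richness; the `repeats`
  argument mitigates this at the cost of departing from the emulated
  design.
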