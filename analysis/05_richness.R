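#!/usr/bin/env Rscript
# Rarefied gene richness and its regression models: richness against
# baseline BMI (adjusted for sex, age), and richness against future
# weight-loss group (adjusted for baseline BMI, sex, age).
#
# The dual-regression count table from 03/04 keeps every cluster abundant in
# every sample (its job is coefficient recovery), so richness would be flat.
# Here the gene-cluster table is simulated with the structure richness
# analysis actually probes: a long-tailed cluster abundance distribution in
# which subjects with higher baseline BMI carry fewer distinct clusters
# (19 fewer per BMI unit, the cross-sectional signal being emulated), with
# no dependence on the future weight-loss group.

suppressPackageStartupMessages(library(repomics))

cohort <- read.csv("results/cohort_groups.csv")
set.seed(55)

pool <- 6000                               # cluster universe
w <- rlnorm(pool, 0, 1)                    # long-tailed relative abundances
n_present <- round(3000 - 19 * cohort$baseline_bmi + rnorm(105, 0, 100))
counts <- matrix(0L, pool, nrow(cohort),
                 dimnames = list(sprintf("K%05d", seq_len(pool)),
                                 cohort$subject_id))
for (j in seq_len(nrow(cohort))) {
  present <- sample.int(pool, n_present[j])
  counts[present, j] <- rmultinom(1, 150000, w[present])[, 1]
}
clusters <- feature_matrix(counts, "count")

rich <- rarefied_richness(clusters, depth = 100000, seed = 99)
write.csv(data.frame(sample_id = names(rich), richness = rich),
          "results/gene_richness.csv", row.names = FALSE)

models <- richness_models(rich, cohort)
write.csv(models, "results/richness_models.csv", row.names = FALSE)

bmi <- models[models$model == "richness_vs_bmi" &
                models$term == "baseline_bmi", ]
grp <- models[models$model == "richness_vs_group" & models$term == "group", ]
cat(sprintf("Rarefied to 100000 reads: richness %d-%d clusters across %d samples.\n",
            min(rich), max(rich), sum(!is.na(rich))))
cat(sprintf("Richness ~ BMI: %.1f clusters per BMI unit (p = %.3g); simulated slope -19\n",
            bmi$estimate, bmi$p))
cat(sprintf("(rarefaction retains abundant clusters preferentially, so some attenuation is expected).\n"))
cat(sprintf("Richness ~ weight-loss group (BMI-adjusted): p = %.2f.\n", grp$p))
cat("No group effect was simulated, so any significance in this second model\n")
cat("is a false positive of the kind a 5% test produces one time in twenty.\n")
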