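#!/usr/bin/env Rscript
# Dual-regression association analysis over the simulated cohort: for every
# feature, one model targets the weight-loss group (adjusted for baseline
# BMI, age, sex) and one targets baseline BMI (adjusted for age, sex).
# Scores the classification against the simulation truth.

suppressPackageStartupMessages(library(repomics))

cohort <- read.csv("results/cohort_groups.csv")
truth <- read.csv("results/cohort_truth.csv")

counts <- read_feature_csv("results/features_count.csv", "count")
sf <- poscounts_size_factors(counts)
write.csv(data.frame(sample_id = names(sf), size_factor = sf),
          "results/size_factors.csv", row.names = FALSE)

kinds <- c(continuous_log = "gaussian", ordinal = "gaussian",
           count = "negative_binomial")
all_res <- list()
for (kd in names(kinds)) {
  feats <- read_feature_csv(file.path("results",
                                      paste0("features_", kd, ".csv")), kd)
  res <- associate_features(feats, cohort,
                            size_factors = if (kd == "count") sf)
  write.csv(res, file.path("results", paste0("assoc_", kd, ".csv")),
            row.names = FALSE)
  rho <- attr(res, "t_correlation")
  cat(sprintf("%s: %d features, %d bmi_only, %d wl_only, %d both; ",
              kd, nrow(res), sum(res$class == "bmi_only"),
              sum(res$class == "wl_only"), sum(res$class == "both")))
  cat(sprintf("t-statistic correlation rho = %.2f (p = %.2g)\n",
              rho$rho, rho$p))
  all_res[[kd]] <- res
}

combined <- do.call(rbind, all_res)
write.csv(combined[, c("feature_id", "kind", "t_bmi", "t_wl", "class")],
          "results/classification_biplot.csv", row.names = FALSE)

# score against truth: how many truly affected features were recovered?
wl_true <- truth$feature_id[truth$term == "wl"]
bmi_true <- truth$feature_id[truth$term == "bmi"]
called_wl <- combined$feature_id[combined$class %in% c("wl_only", "both")]
called_bmi <- combined$feature_id[combined$class %in% c("bmi_only", "both")]
cat(sprintf("Recovered %d/%d true weight-loss features, %d/%d true BMI features;\n",
            sum(wl_true %in% called_wl), length(wl_true),
            sum(bmi_true %in% called_bmi), length(bmi_true)))
null_ids <- setdiff(combined$feature_id, c(wl_true, bmi_true))
cat(sprintf("false positives among %d null features: %d\n",
            length(null_ids),
            sum(!combined$class[combined$feature_id %in% null_ids] %in%
                  "neither")))
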