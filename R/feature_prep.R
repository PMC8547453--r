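#' Batch- and QC-normalize a raw metabolite matrix
#'
#' Within each batch every metabolite is median-scaled over the batch's study
#' samples (so the within-batch median of the scaled values is 1), then
#' divided by the mean scaled value of the batch's quality-control samples
#' for that metabolite to remove batch effects. Remaining missing cells are
#' imputed to the minimum observed (normalized) value of the metabolite
#' across the whole data set, and all values are log-transformed. QC samples
#' are removed from the output.
#'
#' @param raw A `feature_matrix` (any kind accepted; raw values >= 0 or NA)
#'   with `batch` and `qc` attributes, or a plain matrix plus `batch`/`qc`
#'   arguments.
#' @param batch Named character vector sample -> batch (taken from `raw` if
#'   attached).
#' @param qc Named logical vector marking QC samples (taken from `raw` if
#'   attached).
#' @param log_base Base of the final log transform (default `exp(1)`).
#'
#' @return A complete `feature_matrix` of kind `continuous_log` over the
#'   study (non-QC) samples; metabolites missing in all study samples are
#'   dropped with a warning.
#' @export
normalize_metabolites <- function(raw, batch = attr(raw, "batch"),
                                  qc = attr(raw, "qc"),
                                  log_base = exp(1)) {
  values <- unclass(raw)[, , drop = FALSE]
  if (is.null(batch)) stop("no batch labels supplied")
  if (is.null(qc)) stop("no QC flags supplied")
  batch <- batch[colnames(values)]
  qc <- qc[colnames(values)]
  if (anyNA(batch) || anyNA(qc)) {
    stop("every sample needs a batch label and a QC flag")
  }
  out <- values
  for (b in unique(batch)) {
    in_b <- batch == b
    if (!any(in_b & qc)) {
      stop("batch '", b, "' has no quality-control samples")
    }
    study <- in_b & !qc
    med <- apply(values[, study, drop = FALSE], 1, stats::median,
                 na.rm = TRUE)
    scaled <- sweep(values[, in_b, drop = FALSE], 1, med, "/")
    qc_mean <- rowMeans(scaled[, qc[in_b], drop = FALSE], na.rm = TRUE)
    out[, in_b] <- sweep(scaled, 1, qc_mean, "/")
  }
  out <- out[, !qc, drop = FALSE]
  all_missing <- apply(out, 1, function(v) all(is.na(v)))
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " metabolite(s) missing in all study samples")
    out <- out[!all_missing, , drop = FALSE]
  }
  out <- impute_minimum(out)
  feature_matrix(log(out, base = log_base), kind = "continuous_log")
}

# replace each feature's missing cells by its minimum observed value;
# observed cells are never touched
impute_minimum <- function(values) {
  for (i in which(apply(values, 1, anyNA))) {
    v <- values[i, ]
    values[i, is.na(v)] <- min(v, na.rm = TRUE)
  }
  values
}

#' Prepare a protein abundance matrix for association models
#'
#' Drops proteins whose missing fraction is at or above
#' `max_missing_fraction`, imputes remaining missing cells to the protein's
#' minimum observed value, and log-transforms.
#'
#' @param raw `feature_matrix` or matrix of raw abundances (>= 0 or NA).
#' @param max_missing_fraction Features with a missing fraction >= this are
#'   dropped (default 0.05, i.e. "less than 5% missing" retained).
#' @param log_base Base of the log transform (default `exp(1)`).
#'
#' @return Complete `feature_matrix` of kind `continuous_log`.
#' @export
prepare_proteins <- function(raw, max_missing_fraction = 0.05,
                             log_base = exp(1)) {
  values <- unclass(raw)[, , drop = FALSE]
  miss <- rowMeans(is.na(values))
  values <- values[miss < max_missing_fraction, , drop = FALSE]
  values <- impute_minimum(values)
  feature_matrix(log(values, base = log_base), kind = "continuous_log")
}

#' Within-subject SRM log ratios (follow-up minus baseline)
#'
#' Targeted-proteomics change scores: each protein's light/heavy abundance
#' ratio is compared across the intervention, `log(followup) -
#' log(baseline)` per protein and subject.
#'
#' @param baseline,followup `feature_matrix` objects (or matrices) with
#'   identical features and samples; values must be positive ratios.
#' @param log_base Base of the logs (default `exp(1)`).
#'
#' @return `feature_matrix` of kind `continuous_log` holding the deltas.
#' @export
srm_log_ratios <- function(baseline, followup, log_base = exp(1)) {
  b <- unclass(baseline)[, , drop = FALSE]
  f <- unclass(followup)[, , drop = FALSE]
  if (!identical(dimnames(b), dimnames(f))) {
    stop("baseline and follow-up matrices must share features and samples")
  }
  bad <- which(!(b > 0) | !(f > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive L/H ratio at feature '", rownames(b)[bad[1, 1]],
         "', sample '", colnames(b)[bad[1, 2]], "'")
  }
  feature_matrix(log(f, base = log_base) - log(b, base = log_base),
                 kind = "continuous_log")
}

#' Aggregate ORF counts to annotation-term gene clusters
#'
#' Sums member-ORF counts per annotation term (KO, CAZy) and sample. ORFs
#' without an annotation are pooled under the reserved term `"unannotated"`,
#' which is kept for library-size accounting but should be excluded from
#' cluster-level analyses.
#'
#' @param orf_counts `feature_matrix` of kind `count` (ORFs x samples).
#' @param orf_to_term Named character vector ORF -> term; ORFs absent from
#'   the map (or mapped to NA/"") are unannotated.
#'
#' @return `feature_matrix` of kind `count` at term level, with the
#'   `"unannotated"` row last when present; empty (plus a warning) when no
#'   ORF is annotated.
#' @export
aggregate_gene_clusters <- function(orf_counts, orf_to_term) {
  values <- unclass(orf_counts)[, , drop = FALSE]
  term <- orf_to_term[rownames(values)]
  term[is.na(term) | term == ""] <- "unannotated"
  agg <- rowsum(values, group = term)
  terms <- setdiff(rownames(agg), "unannotated")
  if (length(terms) == 0) {
    warning("no annotated ORFs; cluster table is empty")
  }
  agg <- agg[c(sort(terms), intersect("unannotated", rownames(agg))), ,
             drop = FALSE]
  feature_matrix(agg, kind = "count")
}

#' Median-of-ratios size factors tolerant of zero counts ("poscounts")
#'
#' Per feature, a reference pseudo-abundance is the geometric mean computed
#' over the feature's positive counts but divided by the total number of
#' samples; each sample's factor is the median, over features with a positive
#' reference and a positive count in that sample, of count/reference.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts `feature_matrix` of kind `count` (or integer matrix),
#'   >= 2 samples, each with at least one positive count.
#'
#' @return Named numeric vector of per-sample size factors (geometric
#'   mean 1).
#' @export
poscounts_size_factors <- function(counts) {
  values <- unclass(counts)[, , drop = FALSE]
  if (ncol(values) < 2) stop("size factors need at least 2 samples")
  zero_samples <- colnames(values)[colSums(values > 0) == 0]
  if (length(zero_samples) > 0) {
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "))
  }
  n <- ncol(values)
  log_ref <- apply(values, 1, function(v) sum(log(v[v > 0])) / n)
  ref <- exp(log_ref)
  factors <- apply(values, 2, function(v) {
    ok <- ref > 0 & v > 0
    stats::median(v[ok] / ref[ok])
  })
  factors / exp(mean(log(factors)))
}

#' Rarefied gene richness at a fixed sequencing depth
#'
#' Subsamples each sample's assigned-cluster counts without replacement down
#' to `depth` reads (one seeded draw) and counts the clusters still observed.
#' Samples with fewer total assigned reads than `depth` are excluded with a
#' warning rather than aborting the run.
#'
#' @param cluster_counts `feature_matrix` of kind `count` (clusters x
#'   samples); pass assigned clusters only (drop the `"unannotated"` row).
#' @param depth Target depth in reads (default 100000).
#' @param seed Integer seed making the draw reproducible.
#' @param repeats Number of independent draws to average (default 1, a
#'   single rarefaction); with repeats > 1 the mean richness is returned.
#'
#' @return Named numeric vector of per-sample richness; NA for excluded
#'   samples.
#' @export
rarefied_richness <- function(cluster_counts, depth = 100000, seed = NULL,
                              repeats = 1) {
  values <- unclass(cluster_counts)[, , drop = FALSE]
  totals <- colSums(values)
  out <- stats::setNames(rep(NA_real_, ncol(values)), colnames(values))
  ok <- totals >= depth
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " sample(s) with fewer than ", depth,
            " assigned reads: ", paste(colnames(values)[!ok], collapse = ", "))
  }
  if (!any(ok)) return(out)
  if (!is.null(seed)) set.seed(seed)
  comm <- t(values[, ok, drop = FALSE])  # vegan wants samples x features
  rich <- replicate(repeats, {
    # rrarefy nudges about matrices whose smallest positive count exceeds 1;
    # aggregated cluster counts routinely look like that, so silence it
    sub <- withCallingHandlers(
      vegan::rrarefy(comm, sample = depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    rowSums(sub > 0)
  })
  out[ok] <- rowMeans(matrix(rich, nrow = sum(ok)))
  out
}
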