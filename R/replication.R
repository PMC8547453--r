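#' Sliding-window mean smoothing of binned coverage
#'
#' Centered moving average over `window` bins; at the contig ends the window
#' is truncated to the available bins, so output length equals input length.
#' For an even window the extra bin is taken to the right. `window = 1` is
#' the identity.
#'
#' @param values Numeric vector of binned mean depths.
#' @param window Window width in bins (default 50; at 100-bp bins this is a
#'   5,000-bp window).
#'
#' @return Numeric vector of smoothed depths, same length as `values`.
#' @export
smooth_coverage <- function(values, window = 50) {
  stopifnot(window >= 1, length(values) > 0)
  n <- length(values)
  if (window > n) {
    stop("smoothing window (", window, " bins) exceeds the number of bins (",
         n, "); the contig is too short for this window")
  }
  if (window == 1) return(values)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, values))
  lo <- pmax(1L, seq_len(n) - left)
  hi <- pmin(n, seq_len(n) + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate a contig replication rate from smoothed coverage
#'
#' iRep-style estimator: coverage bins are sorted ascending, a symmetric
#' fraction of the lowest and highest bins is trimmed, remaining values are
#' log2-transformed (non-positive bins dropped and counted), and an ordinary
#' least-squares line is fit against the sorted-rank position rescaled to
#' \[0, 1\] over the original pre-trim rank range. The replication rate is
#' `2^slope`, i.e. the fitted peak-to-trough coverage ratio across the sorted
#' profile. A flat profile gives rate 1; actively replicating populations
#' show origin-proximal coverage excess and rate > 1.
#'
#' @param smoothed Numeric vector of smoothed bin depths, or a
#'   `binned_coverage` object (its `values` are used as-is; smooth first with
#'   [smooth_coverage()]).
#' @param trim_fraction Fraction of sorted bins trimmed from each tail
#'   (default 0.05).
#' @param min_r2 Optional minimum r-squared for `passed_qc`; `NULL` (default)
#'   disables the quality gate and only reports the fit quality.
#' @param contig_id,sample_id Identifiers carried into the result.
#'
#' @return One-row data.frame with columns `contig_id`, `sample_id`, `rate`,
#'   `slope`, `intercept`, `r_squared`, `n_bins` (bins used in the fit),
#'   `n_zero_dropped`, `mean_coverage`, `trim_fraction`, `passed_qc`, and
#'   `reason` (non-empty when the estimate was refused; then `rate` is NA).
#' @export
estimate_rate <- function(smoothed, trim_fraction = 0.05, min_r2 = NULL,
                          contig_id = NA_character_,
                          sample_id = NA_character_) {
  if (inherits(smoothed, "binned_coverage")) {
    if (is.na(contig_id)) contig_id <- smoothed$contig_id
    smoothed <- smoothed$values
  }
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  refuse <- function(reason) {
    data.frame(contig_id = contig_id, sample_id = sample_id, rate = NA_real_,
               slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
               n_bins = 0L, n_zero_dropped = 0L,
               mean_coverage = mean(smoothed), trim_fraction = trim_fraction,
               passed_qc = FALSE, reason = reason)
  }
  n <- length(smoothed)
  if (n == 0 || all(smoothed == 0)) return(refuse("all_zero_coverage"))
  sorted <- sort(smoothed)
  x <- (seq_len(n) - 1) / (n - 1)
  k <- floor(trim_fraction * n)
  keep <- seq.int(k + 1L, n - k)
  sorted <- sorted[keep]
  x <- x[keep]
  pos <- sorted > 0
  n_zero <- sum(!pos)
  sorted <- sorted[pos]
  x <- x[pos]
  if (length(sorted) < 10) return(refuse("fewer_than_10_usable_bins"))
  y <- log2(sorted)
  if (all(y == y[1])) {
    # perfectly flat sorted profile: slope 0, rate 1, fit quality undefined
    out <- data.frame(contig_id = contig_id, sample_id = sample_id,
                      rate = 1, slope = 0, intercept = y[1],
                      r_squared = NA_real_, n_bins = length(y),
                      n_zero_dropped = n_zero, mean_coverage = mean(smoothed),
                      trim_fraction = trim_fraction, passed_qc = TRUE,
                      reason = "constant_coverage")
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  passed <- is.null(min_r2) || r2 >= min_r2
  data.frame(contig_id = contig_id, sample_id = sample_id,
             rate = 2^slope, slope = slope, intercept = intercept,
             r_squared = r2, n_bins = length(y), n_zero_dropped = n_zero,
             mean_coverage = mean(smoothed), trim_fraction = trim_fraction,
             passed_qc = passed, reason = "")
}

#' Per-sample contig replication rates from binned coverage profiles
#'
#' Full inference chain for one sample: eligibility filtering on the
#' unsmoothed bins (length and mean-coverage thresholds), sliding-window
#' smoothing, and the sorted-slope rate estimate per contig.
#'
#' @param profiles List of `binned_coverage` objects for one sample.
#' @param sample_id Sample identifier carried into the estimates.
#' @param window Smoothing window in bins (default 50).
#' @param trim_fraction,min_r2 Passed to [estimate_rate()].
#' @param min_irep_length,min_mean_cov Eligibility thresholds, see
#'   [filter_contigs()].
#'
#' @return List with `estimates` (data.frame of per-contig estimates) and
#'   `exclusions` (the filter log).
#' @export
replication_rates <- function(profiles, sample_id = NA_character_,
                              window = 50, trim_fraction = 0.05,
                              min_r2 = NULL, min_irep_length = 11000,
                              min_mean_cov = 2.0) {
  flt <- filter_contigs(profiles, min_irep_length = min_irep_length,
                        min_mean_cov = min_mean_cov)
  est <- lapply(flt$eligible, function(p) {
    estimate_rate(smooth_coverage(p$values, window),
                  trim_fraction = trim_fraction, min_r2 = min_r2,
                  contig_id = p$contig_id, sample_id = sample_id)
  })
  estimates <- if (length(est)) do.call(rbind, est) else
    estimate_rate(numeric(0))[0, ]
  list(estimates = estimates, exclusions = flt$log)
}

#' Aggregate contig replication estimates to taxon-level per-sample means
#'
#' Unweighted mean of the per-contig rates within each (sample, taxon) cell
#' at the requested rank; contigs unclassified at that rank (or absent from
#' the taxonomy table) are pooled under `NA`. A per-sample overall mean
#' across all contigs is returned alongside.
#'
#' @param estimates Data.frame of replication estimates (needs `contig_id`,
#'   `sample_id`, `rate`); rows with NA rate are dropped.
#' @param taxa Data.frame with `contig_id` and rank columns
#'   (`superkingdom`, `phylum`, ...); empty string or NA means unclassified.
#' @param level Rank at which to aggregate (default `"phylum"`).
#'
#' @return List with `by_taxon` (data.frame `sample_id`, `taxon`,
#'   `mean_rate`, `n_contigs`; `taxon` is NA for unclassified) and `overall`
#'   (data.frame `sample_id`, `mean_rate`, `n_contigs`).
#' @export
aggregate_by_taxon <- function(estimates, taxa, level = "phylum") {
  estimates <- estimates[!is.na(estimates$rate), , drop = FALSE]
  if (nrow(estimates) == 0) {
    warning("no usable replication estimates to aggregate")
    empty <- data.frame(sample_id = character(0), taxon = character(0),
                        mean_rate = numeric(0), n_contigs = integer(0))
    return(list(by_taxon = empty, overall = empty[, -2]))
  }
  if (!level %in% names(taxa)) {
    stop("taxonomy table has no '", level, "' column")
  }
  lab <- taxa[[level]][match(estimates$contig_id, taxa$contig_id)]
  lab[!is.na(lab) & lab == ""] <- NA_character_
  key <- interaction(estimates$sample_id, addNA(factor(lab)), drop = TRUE)
  by_taxon <- do.call(rbind, lapply(split(seq_len(nrow(estimates)), key),
    function(idx) {
      data.frame(sample_id = estimates$sample_id[idx[1]],
                 taxon = if (is.na(lab[idx[1]])) NA_character_ else
                   as.character(lab[idx[1]]),
                 mean_rate = mean(estimates$rate[idx]),
                 n_contigs = length(idx))
    }))
  rownames(by_taxon) <- NULL
  overall <- do.call(rbind, lapply(split(estimates, estimates$sample_id),
    function(d) data.frame(sample_id = d$sample_id[1],
                           mean_rate = mean(d$rate),
                           n_contigs = nrow(d))))
  rownames(overall) <- NULL
  list(by_taxon = by_taxon, overall = overall)
}

#' Test replication-rate differences between weight-loss groups
#'
#' Linear model `mean_rate ~ group + age + baseline_bmi` fitted on per-sample
#' summaries, i.e. the covariate-adjusted ANOVA for a binary group reduces to
#' the t test of the group coefficient. Covariates with zero variance in a
#' scope are dropped (with a message) so degenerate designs still fit.
#'
#' @param summaries Data.frame of per-sample rate summaries: either the
#'   `overall` table from [aggregate_by_taxon()] (scope `"overall"`) or the
#'   `by_taxon` table (scope `"per_taxon"`, looping phyla including NA).
#' @param meta Cohort metadata (needs `subject_id` or `sample_id`, `group`,
#'   `age`, `baseline_bmi`); each sample must map to exactly one subject.
#' @param scope `"overall"` or `"per_taxon"`.
#'
#' @return Data.frame with one row per scope and model term: `scope`,
#'   `term`, `estimate`, `se`, `t`, `p`, `n`, plus skipped scopes with an NA
#'   row and a `reason`.
#' @export
test_rate_differences <- function(summaries, meta,
                                  scope = c("overall", "per_taxon")) {
  scope <- match.arg(scope)
  id_col <- if ("sample_id" %in% names(meta)) "sample_id" else "subject_id"
  if (anyDuplicated(meta[[id_col]])) {
    stop("metadata maps some samples to more than one subject")
  }
  fit_one <- function(d, label) {
    m <- meta[match(d$sample_id, meta[[id_col]]), ]
    dat <- data.frame(mean_rate = d$mean_rate,
                      group = as.integer(m$group == "weight_loss"),
                      age = m$age, baseline_bmi = m$baseline_bmi)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    covars <- c("group", "age", "baseline_bmi")
    keep <- covars[vapply(dat[covars], function(v) stats::var(v) > 0,
                          logical(1))]
    dropped <- setdiff(covars, keep)
    if (length(dropped)) {
      message("scope ", label, ": dropping zero-variance covariate(s) ",
              paste(dropped, collapse = ", "))
    }
    if (nrow(dat) < length(keep) + 2 || !"group" %in% keep) {
      return(data.frame(scope = label, term = NA_character_,
                        estimate = NA_real_, se = NA_real_, t = NA_real_,
                        p = NA_real_, n = nrow(dat),
                        reason = if (!"group" %in% keep) "constant_group"
                                 else "too_few_samples"))
    }
    fml <- stats::reformulate(keep, response = "mean_rate")
    fit <- stats::lm(fml, data = dat)
    sm <- summary(fit)$coefficients
    data.frame(scope = label, term = rownames(sm), estimate = sm[, 1],
               se = sm[, 2], t = sm[, 3], p = sm[, 4], n = nrow(dat),
               reason = "", row.names = NULL)
  }
  if (scope == "overall") {
    return(fit_one(summaries, "overall"))
  }
  taxa <- unique(summaries$taxon)
  out <- lapply(taxa, function(tx) {
    d <- if (is.na(tx)) summaries[is.na(summaries$taxon), , drop = FALSE]
         else summaries[!is.na(summaries$taxon) & summaries$taxon == tx, ,
                        drop = FALSE]
    fit_one(d, if (is.na(tx)) "NA" else tx)
  })
  do.call(rbind, out)
}
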