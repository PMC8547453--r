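#' Build a model design matrix from cohort metadata
#'
#' Two model targets are supported. The weight-loss model targets the group
#' indicator, correcting for baseline BMI, age and sex; the BMI model drops
#' the group and targets baseline BMI, correcting for age and sex. No
#' interaction terms are fitted.
#'
#' @param meta Cohort metadata with `group` (weight_loss / no_weight_loss),
#'   `baseline_bmi`, `age`, `sex`.
#' @param target `"weight_loss"` or `"baseline_bmi"`.
#' @param sex_reference Sex level coded 0 (default `"female"`).
#'
#' @return List with `design` (model matrix, intercept first), `target_term`
#'   (column name of the target coefficient) and `n`.
#' @export
model_design <- function(meta, target = c("weight_loss", "baseline_bmi"),
                         sex_reference = "female") {
  target <- match.arg(target)
  group <- as.integer(meta$group == "weight_loss")
  sex <- as.integer(meta$sex != sex_reference)
  base <- data.frame(group = group, baseline_bmi = meta$baseline_bmi,
                     age = meta$age, sex = sex)
  cols <- if (target == "weight_loss") {
    c("group", "baseline_bmi", "age", "sex")
  } else {
    c("baseline_bmi", "age", "sex")
  }
  design <- cbind(`(Intercept)` = 1, as.matrix(base[cols]))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(design = design,
       target_term = if (target == "weight_loss") "group" else "baseline_bmi",
       n = nrow(design))
}

#' Per-feature ordinary least squares for a target coefficient
#'
#' Fits every feature against the design by OLS (no empirical-Bayes variance
#' moderation) and reports the target term's coefficient, its standard error
#' from the Fisher information of the fit, the t statistic (coefficient /
#' standard error) and the two-sided p value from the t distribution with
#' residual degrees of freedom. Ordinal responses are treated as numeric.
#'
#' @param features `feature_matrix` (kind `continuous_log` or `ordinal`) or
#'   numeric matrix, features x samples, no missing values.
#' @param design Model matrix from [model_design()] (or list as returned).
#' @param target_term Column of `design` to report (taken from the
#'   `model_design` list when one is passed).
#'
#' @return Data.frame with `feature_id`, `coef`, `se`, `t`, `p`,
#'   `zero_variance` (flag; such features get coef 0 and NA t/p).
#' @export
fit_gaussian <- function(features, design, target_term = NULL) {
  values <- unclass(features)[, , drop = FALSE]
  if (anyNA(values)) stop("feature matrix has missing values; prepare first")
  if (is.list(design)) {
    if (is.null(target_term)) target_term <- design$target_term
    design <- design$design
  }
  stopifnot(ncol(values) == nrow(design), target_term %in% colnames(design))
  fit <- limma::lmFit(values, design)
  df <- fit$df.residual
  sigma <- fit$sigma
  coef <- fit$coefficients[, target_term]
  se <- fit$stdev.unscaled[, target_term] * sigma
  tt <- coef / se
  p <- 2 * stats::pt(-abs(tt), df)
  zero_var <- apply(values, 1, function(v) stats::var(v) == 0)
  coef[zero_var] <- 0
  tt[zero_var] <- NA_real_
  p[zero_var] <- NA_real_
  se[zero_var] <- NA_real_
  data.frame(feature_id = rownames(values), coef = unname(coef),
             se = unname(se), t = unname(tt), p = unname(p),
             zero_variance = unname(zero_var), row.names = NULL)
}

# method-of-moments dispersion for the NB fallback: pooled excess variance
# of Pearson residuals around the Poisson fit
mom_dispersion <- function(y, mu) {
  num <- sum((y - mu)^2 - mu)
  den <- sum(mu^2)
  max(num / den, 1e-8)
}

#' Per-feature negative-binomial regression with a library-size offset
#'
#' Fits each count feature with an NB log-link regression, offset by the log
#' size factor; the dispersion is estimated per feature by maximum
#' likelihood, falling back to a method-of-moments estimate when the ML fit
#' fails to converge. Reports the Wald pseudo-t (coefficient / standard
#' error) with a two-sided normal p value.
#'
#' @param counts `feature_matrix` of kind `count` (or integer matrix).
#' @param size_factors Positive per-sample size factors, e.g. from
#'   [poscounts_size_factors()].
#' @param design Model matrix or [model_design()] list.
#' @param target_term Column of the design to report.
#'
#' @return Data.frame with `feature_id`, `coef` (natural-log scale), `se`,
#'   `t`, `p`, `status` (`"ok"`, `"mom_fallback"`, `"all_zero"`,
#'   `"failed"`); failed and all-zero features carry NA statistics and are
#'   meant to be excluded from FDR adjustment.
#' @export
fit_negative_binomial <- function(counts, size_factors, design,
                                  target_term = NULL) {
  values <- unclass(counts)[, , drop = FALSE]
  if (is.list(design)) {
    if (is.null(target_term)) target_term <- design$target_term
    design <- design$design
  }
  stopifnot(all(size_factors > 0), ncol(values) == nrow(design))
  off <- log(size_factors)
  X <- design[, colnames(design) != "(Intercept)", drop = FALSE]
  j <- match(target_term, colnames(X))
  rows <- lapply(seq_len(nrow(values)), function(i) {
    y <- values[i, ]
    if (all(y == 0)) {
      return(data.frame(feature_id = rownames(values)[i], coef = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        status = "all_zero"))
    }
    dat <- data.frame(y = y, X, off = off)
    fml <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = "+"),
                                   "+ offset(off)"))
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = dat)),
                    error = function(e) NULL)
    status <- "ok"
    if (is.null(fit) || !fit$converged) {
      pois <- tryCatch(
        suppressWarnings(stats::glm(fml, data = dat, family = stats::poisson())),
        error = function(e) NULL)
      if (is.null(pois)) {
        return(data.frame(feature_id = rownames(values)[i], coef = NA_real_,
                          se = NA_real_, t = NA_real_, p = NA_real_,
                          status = "failed"))
      }
      alpha <- mom_dispersion(y, stats::fitted(pois))
      fit <- tryCatch(
        suppressWarnings(stats::glm(fml, data = dat,
                                    family = MASS::negative.binomial(1 / alpha))),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        return(data.frame(feature_id = rownames(values)[i], coef = NA_real_,
                          se = NA_real_, t = NA_real_, p = NA_real_,
                          status = "failed"))
      }
      status <- "mom_fallback"
    }
    sm <- summary(fit)$coefficients
    term_row <- match(target_term, rownames(sm))
    co <- sm[term_row, 1]
    se <- sm[term_row, 2]
    z <- co / se
    data.frame(feature_id = rownames(values)[i], coef = co, se = se, t = z,
               p = 2 * stats::pnorm(-abs(z)), status = status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement. FDR control is
#' applied separately within each data type; this function adjusts exactly
#' the vector it is given, so callers own that contract.
#'
#' @param pvalues Numeric vector of p values in \[0, 1\] (NA passed through).
#' @param method Adjustment method (default `"BH"`).
#'
#' @return Adjusted p values, same length and order.
#' @export
adjust_fdr <- function(pvalues, method = "BH") {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = method)
}

#' Classify features by their dual-model significance pattern
#'
#' @param fdr_bmi,fdr_wl BH-adjusted p values from the BMI-target and
#'   weight-loss-target models.
#' @param alpha Significance threshold on the FDR scale (default 0.05).
#'
#' @return Character vector with levels `bmi_only`, `wl_only`, `both`,
#'   `neither` (NA fdr in a slot counts as not significant).
#' @export
classify_features <- function(fdr_bmi, fdr_wl, alpha = 0.05) {
  sig_bmi <- !is.na(fdr_bmi) & fdr_bmi < alpha
  sig_wl <- !is.na(fdr_wl) & fdr_wl < alpha
  out <- rep("neither", length(fdr_bmi))
  out[sig_bmi & !sig_wl] <- "bmi_only"
  out[!sig_bmi & sig_wl] <- "wl_only"
  out[sig_bmi & sig_wl] <- "both"
  out
}

#' Pearson correlation between the two models' t statistics
#'
#' @param t_bmi,t_wl Equal-length numeric vectors (length >= 3, no NA).
#' @return List with `rho`, `p`, and `flag` (`"zero_variance"` when the
#'   correlation is undefined, in which case `rho` is NA).
#' @export
correlate_tstats <- function(t_bmi, t_wl) {
  stopifnot(length(t_bmi) == length(t_wl), length(t_bmi) >= 3)
  if (anyNA(t_bmi) || anyNA(t_wl)) stop("t statistics contain NA")
  if (stats::var(t_bmi) == 0 || stats::var(t_wl) == 0) {
    return(list(rho = NA_real_, p = NA_real_, flag = "zero_variance"))
  }
  ct <- stats::cor.test(t_bmi, t_wl, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, flag = "")
}

#' Dual-regression association analysis for one data type
#'
#' The core Fig-4-style analysis: every feature is fitted twice, once with
#' the weight-loss group as the target (adjusted for baseline BMI, age, sex)
#' and once with baseline BMI as the target (adjusted for age, sex, no group
#' term). P values are BH-adjusted within the data type for each model
#' separately, and each feature is classified by its significance pattern.
#'
#' @param features `feature_matrix`; kinds `continuous_log` and `ordinal`
#'   use OLS, kind `count` uses NB regression with `size_factors`.
#' @param meta Cohort metadata matched to the matrix columns via
#'   `subject_id`/`sample_id`.
#' @param size_factors Required for `count` features.
#' @param alpha FDR threshold for classification (default 0.05).
#' @param sex_reference Passed to [model_design()].
#'
#' @return Data.frame of association results: `feature_id`, `kind`,
#'   `coef_wl`, `se_wl`, `t_wl`, `p_wl`, `fdr_wl`, `coef_bmi`, `se_bmi`,
#'   `t_bmi`, `p_bmi`, `fdr_bmi`, `class`, `n_samples`, plus a `flag` column
#'   (zero-variance or non-converged features are flagged and classified
#'   `neither`). The Pearson correlation between the two t vectors is
#'   attached as attribute `t_correlation`.
#' @export
associate_features <- function(features, meta, size_factors = NULL,
                               alpha = 0.05, sex_reference = "female") {
  kind <- fm_kind(features)
  id_col <- if ("sample_id" %in% names(meta)) "sample_id" else "subject_id"
  m <- meta[match(colnames(features), meta[[id_col]]), ]
  if (anyNA(m[[id_col]])) {
    stop("some samples have no metadata row: ",
         paste(setdiff(colnames(features), meta[[id_col]]), collapse = ", "))
  }
  des_wl <- model_design(m, "weight_loss", sex_reference)
  des_bmi <- model_design(m, "baseline_bmi", sex_reference)
  if (kind == "count") {
    if (is.null(size_factors)) stop("count features need size factors")
    sf <- size_factors[colnames(features)]
    fit_wl <- fit_negative_binomial(features, sf, des_wl)
    fit_bmi <- fit_negative_binomial(features, sf, des_bmi)
    flag <- ifelse(fit_wl$status %in% c("all_zero", "failed") |
                     fit_bmi$status %in% c("all_zero", "failed"),
                   paste0(fit_wl$status, "/", fit_bmi$status), "")
  } else {
    fit_wl <- fit_gaussian(features, des_wl)
    fit_bmi <- fit_gaussian(features, des_bmi)
    flag <- ifelse(fit_wl$zero_variance, "zero_variance", "")
  }
  usable <- flag == ""
  fdr_wl <- fdr_bmi <- rep(NA_real_, nrow(fit_wl))
  fdr_wl[usable] <- adjust_fdr(fit_wl$p[usable])
  fdr_bmi[usable] <- adjust_fdr(fit_bmi$p[usable])
  out <- data.frame(feature_id = fit_wl$feature_id, kind = kind,
                    coef_wl = fit_wl$coef, se_wl = fit_wl$se,
                    t_wl = fit_wl$t, p_wl = fit_wl$p, fdr_wl = fdr_wl,
                    coef_bmi = fit_bmi$coef, se_bmi = fit_bmi$se,
                    t_bmi = fit_bmi$t, p_bmi = fit_bmi$p, fdr_bmi = fdr_bmi,
                    class = classify_features(fdr_bmi, fdr_wl, alpha),
                    n_samples = ncol(features), flag = flag)
  if (sum(usable) >= 3) {
    attr(out, "t_correlation") <- correlate_tstats(fit_bmi$t[usable],
                                                   fit_wl$t[usable])
  }
  out
}

#' Association of SRM protein change scores with weight loss
#'
#' Per protein, OLS of the within-subject log ratio (follow-up minus
#' baseline) on group + baseline BMI + age + sex, with BH adjustment within
#' the SRM panel and a significance call at `alpha_fdr`.
#'
#' @param deltas `feature_matrix` of log ratios from [srm_log_ratios()].
#' @param meta Cohort metadata (one row per subject).
#' @param alpha_fdr FDR threshold for the significant set (default 0.1).
#' @param sex_reference Passed to [model_design()].
#'
#' @return Data.frame `feature_id`, `coef`, `se`, `t`, `p`, `fdr`,
#'   `significant`.
#' @export
srm_change_model <- function(deltas, meta, alpha_fdr = 0.1,
                             sex_reference = "female") {
  id_col <- if ("sample_id" %in% names(meta)) "sample_id" else "subject_id"
  m <- meta[match(colnames(deltas), meta[[id_col]]), ]
  des <- model_design(m, "weight_loss", sex_reference)
  fit <- fit_gaussian(deltas, des)
  fit$fdr <- rep(NA_real_, nrow(fit))
  fit$fdr[!fit$zero_variance] <- adjust_fdr(fit$p[!fit$zero_variance])
  fit$significant <- !is.na(fit$fdr) & fit$fdr < alpha_fdr
  fit
}

#' Gene-richness regression models
#'
#' Model 1 regresses richness on baseline BMI (adjusted for sex and age),
#' the cross-sectional richness-BMI association; model 2 adds the
#' weight-loss group as target (adjusted for baseline BMI, sex, age), asking
#' whether baseline richness predicts weight-loss success.
#'
#' @param richness Named per-sample richness vector (names are subject or
#'   sample ids); NA entries dropped.
#' @param meta Cohort metadata.
#' @param sex_reference Passed to [model_design()].
#'
#' @return Data.frame with one row per model and term: `model`
#'   (`richness_vs_bmi` / `richness_vs_group`), `term`, `estimate`, `se`,
#'   `t`, `p`, `n`.
#' @export
richness_models <- function(richness, meta, sex_reference = "female") {
  id_col <- if ("sample_id" %in% names(meta)) "sample_id" else "subject_id"
  richness <- richness[!is.na(richness)]
  m <- meta[match(names(richness), meta[[id_col]]), ]
  dat <- data.frame(richness = as.numeric(richness),
                    group = as.integer(m$group == "weight_loss"),
                    baseline_bmi = m$baseline_bmi, age = m$age,
                    sex = as.integer(m$sex != sex_reference))
  if (stats::var(dat$richness) == 0) {
    return(data.frame(model = c("richness_vs_bmi", "richness_vs_group"),
                      term = NA_character_, estimate = 0, se = NA_real_,
                      t = NA_real_, p = NA_real_, n = nrow(dat),
                      flag = "zero_variance"))
  }
  tidy_fit <- function(fml, label) {
    sm <- summary(stats::lm(fml, data = dat))$coefficients
    data.frame(model = label, term = rownames(sm), estimate = sm[, 1],
               se = sm[, 2], t = sm[, 3], p = sm[, 4], n = nrow(dat),
               flag = "", row.names = NULL)
  }
  rbind(tidy_fit(richness ~ baseline_bmi + sex + age, "richness_vs_bmi"),
        tidy_fit(richness ~ group + baseline_bmi + sex + age,
                 "richness_vs_group"))
}

#' Baseline group comparisons and marker correlation matrix
#'
#' Per marker, a Welch unequal-variance t test between the weight-loss and
#' no-weight-loss groups; plus the pairwise Pearson correlation matrix of
#' the markers with product-moment tests.
#'
#' @param markers `feature_matrix` (markers x samples) of baseline values.
#' @param meta Cohort metadata.
#'
#' @return List with `tests` (data.frame `marker`, `t`, `p`, `mean_wl`,
#'   `mean_nwl`, `skipped`), `cor` (marker x marker Pearson matrix) and
#'   `cor_p` (matching p-value matrix).
#' @export
baseline_group_tests <- function(markers, meta) {
  values <- unclass(markers)[, , drop = FALSE]
  id_col <- if ("sample_id" %in% names(meta)) "sample_id" else "subject_id"
  m <- meta[match(colnames(values), meta[[id_col]]), ]
  wl <- m$group == "weight_loss"
  nwl <- m$group == "no_weight_loss"
  tests <- do.call(rbind, lapply(rownames(values), function(f) {
    a <- values[f, wl]
    b <- values[f, nwl]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
      return(data.frame(marker = f, t = NA_real_, p = NA_real_,
                        mean_wl = mean(a, na.rm = TRUE),
                        mean_nwl = mean(b, na.rm = TRUE), skipped = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(marker = f, t = unname(tt$statistic), p = tt$p.value,
               mean_wl = mean(a, na.rm = TRUE),
               mean_nwl = mean(b, na.rm = TRUE), skipped = FALSE)
  }))
  cm <- stats::cor(t(values), use = "pairwise.complete.obs")
  k <- nrow(values)
  cp <- matrix(NA_real_, k, k, dimnames = dimnames(cm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { cp[i, j] <- 0; next }
      ct <- tryCatch(stats::cor.test(values[i, ], values[j, ]),
                     error = function(e) NULL)
      if (!is.null(ct)) cp[i, j] <- ct$p.value
    }
  }
  list(tests = tests, cor = cm, cor_p = cp)
}

#' Paired baseline-versus-follow-up tests per marker
#'
#' Paired t test of follow-up against baseline within a group of subjects,
#' one marker at a time (the paired analogue of the Welch comparisons used
#' for baseline chemistries).
#'
#' @param baseline,followup `feature_matrix` objects with identical
#'   features/samples.
#' @return Data.frame `marker`, `mean_diff`, `t`, `p`.
#' @export
paired_followup_tests <- function(baseline, followup) {
  b <- unclass(baseline)[, , drop = FALSE]
  f <- unclass(followup)[, , drop = FALSE]
  if (!identical(dimnames(b), dimnames(f))) {
    stop("baseline and follow-up matrices must match")
  }
  do.call(rbind, lapply(rownames(b), function(mk) {
    tt <- stats::t.test(f[mk, ], b[mk, ], paired = TRUE)
    data.frame(marker = mk, mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), p = tt$p.value)
  }))
}
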