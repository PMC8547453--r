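#' Relative weight change in percent of baseline body weight per month
#'
#' Computes the rate used to define the weight-loss phenotype: the change in
#' body weight between baseline and follow-up, expressed as a percentage of
#' the baseline weight, divided by the number of months between the two
#' measurements. Negative values denote weight loss.
#'
#' @param baseline_weight Baseline body weight in kg (positive).
#' @param followup_weight Follow-up body weight in kg.
#' @param months Months between the two measurements (positive).
#'
#' @return Numeric vector of signed rates in percent of baseline body weight
#'   per month.
#' @examples
#' relative_weight_change(100, 92, 8) # -1 %/month
#' @export
relative_weight_change <- function(baseline_weight, followup_weight, months) {
  if (any(!is.finite(baseline_weight)) || any(baseline_weight <= 0)) {
    stop("invalid input: 'baseline_weight' must be positive and finite")
  }
  if (any(!is.finite(months)) || any(months <= 0)) {
    stop("invalid input: 'months' must be positive and finite")
  }
  100 * (followup_weight - baseline_weight) / baseline_weight / months
}

#' Flag subjects with zero variance in their weight series
#'
#' Repeated identical weight reports arise from digital scales when regular
#' weighing is not performed and a stale value is reported again; such
#' subjects are excluded from grouping. Exact equality of the recorded values
#' is required, since the rule targets verbatim repetition of a prior report.
#'
#' @param weight_series Numeric vector of recorded weights (kg).
#'
#' @return One of `"excluded"` (all entries identical), `"retained"`
#'   (any variation), or `"unassessable"` (fewer than 2 entries).
#' @export
exclude_zero_variance <- function(weight_series) {
  weight_series <- weight_series[!is.na(weight_series)]
  if (length(weight_series) < 2) {
    return("unassessable")
  }
  if (all(weight_series == weight_series[1])) "excluded" else "retained"
}

#' Assign weight-loss group from a relative weight-change rate
#'
#' Subjects losing more than `abs(loss_threshold)` percent of body weight per
#' month form the weight-loss group; subjects whose weight stayed essentially
#' flat (no loss, and gain below `stable_threshold` percent per month) form
#' the no-weight-loss group; everyone in between is left unassigned.
#'
#' @param rate Relative weight change in percent per month (signed; negative
#'   is loss), as returned by [relative_weight_change()].
#' @param loss_threshold Rate below which a subject is in the weight-loss
#'   group (default -1 %/month).
#' @param stable_threshold Upper bound (exclusive) on gain for the
#'   no-weight-loss group (default +0.1 %/month); the lower bound is 0.
#'
#' @return Character vector with levels `weight_loss`, `no_weight_loss`,
#'   `unassigned`.
#' @export
assign_group <- function(rate, loss_threshold = -1.0, stable_threshold = 0.1) {
  stopifnot(loss_threshold < 0, stable_threshold > 0)
  out <- rep("unassigned", length(rate))
  out[rate < loss_threshold] <- "weight_loss"
  out[rate >= 0 & rate < stable_threshold] <- "no_weight_loss"
  out[is.na(rate)] <- NA_character_
  out
}

#' Build the analysis cohort table
#'
#' Applies the full subject-selection procedure to a metadata table: computes
#' the relative weight-change rate, excludes zero-variance weight series,
#' and assigns weight-loss groups. Excluded subjects carry a machine-readable
#' reason code and the group label `excluded`.
#'
#' @param meta A data.frame with columns `subject_id`, `sex`, `age`,
#'   `baseline_bmi`, `baseline_weight`, `followup_weight`, `months_between`,
#'   and optionally `weight_series` (semicolon-joined kg values).
#' @param loss_threshold,stable_threshold Grouping thresholds passed to
#'   [assign_group()].
#'
#' @return The input data.frame with added columns `rate` (percent/month),
#'   `group`, and `exclusion_reason` (`""` when not excluded).
#' @export
build_cohort <- function(meta, loss_threshold = -1.0, stable_threshold = 0.1) {
  required <- c("subject_id", "sex", "age", "baseline_bmi",
                "baseline_weight", "followup_weight", "months_between")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  }
  meta$rate <- relative_weight_change(meta$baseline_weight,
                                      meta$followup_weight,
                                      meta$months_between)
  meta$group <- assign_group(meta$rate, loss_threshold, stable_threshold)
  meta$exclusion_reason <- ""
  if ("weight_series" %in% names(meta)) {
    series <- strsplit(as.character(meta$weight_series), ";", fixed = TRUE)
    flags <- vapply(series, function(s) {
      exclude_zero_variance(suppressWarnings(as.numeric(s)))
    }, character(1))
    excl <- flags == "excluded"
    meta$group[excl] <- "excluded"
    meta$exclusion_reason[excl] <- "zero_variance_weights"
  }
  meta
}
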