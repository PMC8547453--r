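#' Construct a feature-by-sample matrix with a declared kind
#'
#' Thin container for multi-omic data: features in rows, samples in columns,
#' with a declared measurement kind driving validation and downstream model
#' choice. `continuous_log` values are analytes modelled on the log scale
#' (metabolites, proteins, SRM light/heavy ratios); `ordinal` values are diet
#' consumption frequencies on the 0-8 scale; `count` values are sequencing
#' counts (non-negative integers).
#'
#' @param values Numeric matrix, features x samples, with dimnames.
#' @param kind One of `"continuous_log"`, `"ordinal"`, `"count"`.
#' @param annotations Optional named list or character vector mapping
#'   feature -> annotation term (KO, CAZy class).
#' @param batch Optional named character vector mapping sample -> batch.
#' @param qc Optional named logical vector marking quality-control samples.
#' @param allow_missing Allow NA cells (pre-normalization data); prepared
#'   `continuous_log` matrices must be complete.
#'
#' @return An object of class `feature_matrix` (the matrix with attributes
#'   `kind`, `annotations`, `batch`, `qc`).
#' @export
feature_matrix <- function(values, kind = c("continuous_log", "ordinal",
                                            "count"),
                           annotations = NULL, batch = NULL, qc = NULL,
                           allow_missing = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature matrix needs feature (row) and sample (column) names")
  }
  obs <- values[!is.na(values)]
  if (!allow_missing && anyNA(values)) {
    stop("missing values present; construct with allow_missing = TRUE ",
         "before preparation")
  }
  if (kind == "count" && length(obs) &&
      (any(obs < 0) || any(obs != round(obs)))) {
    stop("count matrix must hold non-negative integers")
  }
  if (kind == "ordinal" && length(obs) && !all(obs %in% 0:8)) {
    stop("ordinal matrix values must lie in 0..8")
  }
  structure(values, kind = kind, annotations = annotations, batch = batch,
            qc = qc, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples, kind = %s\n",
              nrow(x), ncol(x), attr(x, "kind")))
  invisible(x)
}

fm_kind <- function(x) attr(x, "kind")

# rebuild attributes after subsetting / transformation
fm_like <- function(values, template, kind = fm_kind(template)) {
  feature_matrix(values, kind = kind,
                 annotations = attr(template, "annotations"),
                 batch = attr(template, "batch")[colnames(values)],
                 qc = attr(template, "qc")[colnames(values)],
                 allow_missing = TRUE)
}
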