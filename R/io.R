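#' Write and read the workflow's tabular interchange formats
#'
#' Binned coverage travels as TSV (`contig_id`, `bin_index` 0-based,
#' `mean_depth`); taxonomy as TSV (`contig_id`, `superkingdom`, `phylum`,
#' `class`, `order`, `family`, `genus`; empty = unclassified); feature
#' matrices as CSV with features in rows, first column `feature_id`.
#'
#' @param profiles List of `binned_coverage` objects.
#' @param path Output file path.
#' @name io
NULL

#' @rdname io
#' @export
write_binned_coverage <- function(profiles, path) {
  if (inherits(profiles, "binned_coverage")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(contig_id = p$contig_id,
               bin_index = seq_along(p$values) - 1L,
               mean_depth = p$values)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param bin_width Bin width the profiles were built at.
#' @param contig_lengths Optional named vector of true contig lengths;
#'   defaults to `n_bins * bin_width` per contig (the fully binned extent).
#' @export
read_binned_coverage <- function(path, bin_width = 100,
                                 contig_lengths = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "numeric"))
  lapply(split(tab, tab$contig_id), function(d) {
    d <- d[order(d$bin_index), ]
    len <- if (!is.null(contig_lengths)) contig_lengths[[d$contig_id[1]]]
           else nrow(d) * bin_width
    structure(list(contig_id = d$contig_id[1], contig_length = len,
                   bin_width = bin_width, values = d$mean_depth),
              class = "binned_coverage")
  })
}

#' @rdname io
#' @export
write_depth_tsv <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_taxonomy_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("NA"))
  stopifnot("contig_id" %in% names(tab))
  tab
}

#' @rdname io
#' @param x A `feature_matrix`.
#' @export
write_feature_csv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x),
                   unclass(x)[, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param kind Declared kind of the matrix being read.
#' @export
read_feature_csv <- function(path, kind) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  feature_matrix(m, kind = kind, allow_missing = TRUE)
}
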