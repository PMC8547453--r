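#' Per-base depth from a coordinate-sorted alignment file
#'
#' Counts, at every covered base of every contig, the number of primary,
#' non-supplementary, mapped reads whose alignment spans that base. Bases not
#' reported carry depth 0 by convention.
#'
#' @param alignment_file Path to a BAM (or SAM converted with
#'   [Rsamtools::asBam()]) file, coordinate-sorted and indexed.
#' @param min_mapq Minimum mapping quality for a read to contribute
#'   (default 0, i.e. no filter).
#'
#' @return A depth table: data.frame with columns `contig_id`, `position`
#'   (1-based) and `depth`, sorted by contig then position.
#' @export
depth_from_alignment <- function(alignment_file, min_mapq = 0) {
  if (!file.exists(alignment_file)) {
    stop("alignment file not found: ", alignment_file)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    alignment_file,
    param = Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq))
  cov <- GenomicAlignments::coverage(ga)
  rows <- lapply(names(cov), function(ctg) {
    v <- as.integer(cov[[ctg]])
    pos <- which(v > 0)
    if (length(pos) == 0) return(NULL)
    data.frame(contig_id = ctg, position = pos, depth = v[pos])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(contig_id = character(0), position = integer(0),
                      depth = integer(0)))
  }
  do.call(rbind, rows)
}

#' Read a per-base depth table from TSV
#'
#' @param path Path to a 3-column TSV: contig, 1-based position, depth.
#'   A header row named `contig_id`, `position`, `depth` is accepted but not
#'   required.
#' @return A depth table data.frame (`contig_id`, `position`, `depth`).
#' @export
read_depth_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("contig", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           col.names = c("contig_id", "position", "depth"),
                           colClasses = c("character", "integer", "numeric"))
  names(tab) <- c("contig_id", "position", "depth")
  tab
}

#' Bin per-base depth into fixed-width mean coverage
#'
#' Bins are 0-based half-open intervals `[k*w, (k+1)*w)` over the contig; a
#' trailing partial bin shorter than `bin_width` is dropped (floor rule), so
#' the number of bins is `floor(contig_length / bin_width)`. Positions absent
#' from the depth table contribute depth 0 to their bin's mean.
#'
#' @param depth A depth table (data.frame `contig_id`, `position`, `depth`)
#'   for a single contig, or rows for several contigs from which `contig_id`
#'   selects one.
#' @param contig_length Length of the contig in bp.
#' @param bin_width Bin width in bp (default 100).
#' @param contig_id Contig to bin; defaults to the single contig present.
#'
#' @return An object of class `binned_coverage`: a list with `contig_id`,
#'   `contig_length`, `bin_width`, and `values` (mean depth per bin).
#' @export
bin_coverage <- function(depth, contig_length, bin_width = 100,
                         contig_id = NULL) {
  stopifnot(bin_width >= 1)
  if (contig_length < bin_width) {
    stop("contig shorter than one bin (", contig_length, " < ", bin_width,
         " bp)")
  }
  if (is.null(contig_id)) {
    ids <- unique(depth$contig_id)
    if (length(ids) > 1) {
      stop("depth table holds several contigs; give 'contig_id'")
    }
    contig_id <- if (length(ids) == 1) ids else NA_character_
  } else {
    depth <- depth[depth$contig_id == contig_id, , drop = FALSE]
  }
  n_bins <- contig_length %/% bin_width
  values <- numeric(n_bins)
  if (nrow(depth) > 0) {
    pos <- depth$position
    keep <- pos >= 1 & pos <= n_bins * bin_width
    bin <- (pos[keep] - 1L) %/% bin_width + 1L
    sums <- rowsum(depth$depth[keep], bin)
    values[as.integer(rownames(sums))] <- sums[, 1] / bin_width
  }
  structure(list(contig_id = contig_id, contig_length = contig_length,
                 bin_width = bin_width, values = values),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("<binned_coverage> %s: %d bp, %d bins of %d bp, mean %.2fx\n",
              x$contig_id, x$contig_length, length(x$values), x$bin_width,
              mean(x$values)))
  invisible(x)
}

#' Apply contig eligibility filters for replication inference
#'
#' A contig is eligible when its length is at least `min_irep_length` bp and
#' its mean (unsmoothed) bin coverage is at least `min_mean_cov`; both
#' thresholds are inclusive. Profiles shorter than `min_profile_length` are
#' not expected here (profiles are typically only extracted above that
#' length) but are logged the same way.
#'
#' @param profiles A list of `binned_coverage` objects.
#' @param min_profile_length Minimum length for a profile to be considered at
#'   all (default 5000 bp).
#' @param min_irep_length Minimum contig length for rate inference
#'   (default 11000 bp).
#' @param min_mean_cov Minimum mean coverage in x-fold (default 2.0).
#'
#' @return A list with `eligible` (the passing subset of `profiles`) and
#'   `log`, a data.frame (`contig_id`, `contig_length`, `mean_coverage`,
#'   `eligible`, `reason`) where `reason` is a semicolon-joined code among
#'   `length` and `coverage` (empty when eligible).
#' @export
filter_contigs <- function(profiles, min_profile_length = 5000,
                           min_irep_length = 11000, min_mean_cov = 2.0) {
  if (inherits(profiles, "binned_coverage")) profiles <- list(profiles)
  log <- do.call(rbind, lapply(profiles, function(p) {
    reasons <- character(0)
    if (p$contig_length < min_irep_length) reasons <- c(reasons, "length")
    if (mean(p$values) < min_mean_cov) reasons <- c(reasons, "coverage")
    data.frame(contig_id = p$contig_id,
               contig_length = p$contig_length,
               mean_coverage = mean(p$values),
               eligible = length(reasons) == 0,
               reason = paste(reasons, collapse = ";"))
  }))
  if (is.null(log)) {
    log <- data.frame(contig_id = character(0), contig_length = numeric(0),
                      mean_coverage = numeric(0), eligible = logical(0),
                      reason = character(0))
  }
  list(eligible = profiles[log$eligible], log = log)
}
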