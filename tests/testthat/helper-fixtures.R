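# shared fixtures, all built in code at test time

# write a coordinate-sorted SAM of gapless `len`-bp reads and convert to BAM
make_toy_bam <- function(starts, len = 100, contig_len = 400, mapq = 60,
                         contig = "ctg1") {
  mapq <- rep_len(mapq, length(starts))
  ord <- order(starts)
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", contig, "\tLN:", contig_len))
  if (length(starts) > 0) {
    lines <- c(lines, vapply(ord, function(i) {
      paste(paste0("r", i), 0, contig, starts[i], mapq[i],
            paste0(len, "M"), "*", 0, 0, "*", "*", sep = "\t")
    }, character(1)))
  }
  sam <- tempfile(fileext = ".sam")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# brute-force pileup of gapless reads: independent oracle for depth counting
brute_force_depth <- function(starts, len, contig_len) {
  depth <- integer(contig_len)
  for (s in starts) depth[s:(s + len - 1)] <- depth[s:(s + len - 1)] + 1L
  depth
}

# small cohort metadata with both groups present
toy_meta <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             sex = sample(c("female", "male"), n, replace = TRUE),
             age = rnorm(n, 48, 12),
             baseline_bmi = rnorm(n, 29, 5),
             group = rep(c("weight_loss", "no_weight_loss"),
                         length.out = n))
}

# a feature_matrix of iid lognormal-scale values
toy_fm <- function(nf = 5, ns = 8, kind = "continuous_log", seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nf * ns, 2, 0.5), nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("S%02d", seq_len(ns))))
  feature_matrix(m, kind = kind)
}
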