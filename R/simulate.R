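#' Simulate per-base metagenome coverage with a replication gradient
#'
#' Emulates the coverage signature of a replicating circular bacterial
#' genome: expected depth decays exponentially (log2-linearly) with circular
#' distance from the replication origin, from `true_ptr` times the terminus
#' level at the origin down to the terminus level half a genome away. The
#' expectation is scaled so its genome-wide mean equals `mean_depth`, per-base
#' depth is drawn Poisson around it (or taken exactly when `noise = "none"`),
#' and the genome is partitioned left-to-right into the requested contigs.
#'
#' @param genome_length Genome length in bp.
#' @param origin_index 1-based position of the replication origin.
#' @param true_ptr True peak-to-trough coverage ratio (>= 1; 1 = not
#'   replicating).
#' @param mean_depth Genome-wide mean depth in x-fold (default 20).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param contig_lengths Integer vector of contig lengths; their sum must
#'   not exceed `genome_length`.
#' @param seed Optional integer seed.
#'
#' @return List with `depth` (list of depth tables, one per contig, named
#'   `contig_1`, ...), and `truth` (data.frame `contig_id`, `start`, `end`,
#'   `true_ptr`, `expected_span` = max/min expected coverage on the contig).
#' @export
simulate_coverage <- function(genome_length, origin_index = 1, true_ptr,
                              mean_depth = 20,
                              noise = c("poisson", "none"),
                              contig_lengths, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(true_ptr >= 1, genome_length >= 2, mean_depth > 0)
  contig_lengths <- as.integer(contig_lengths)
  if (sum(contig_lengths) > genome_length) {
    stop("contig lengths exceed the genome length")
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- seq_len(genome_length)
  d <- abs(pos - origin_index)
  circ <- pmin(d, genome_length - d)          # circular distance from origin
  x <- circ / (genome_length / 2)             # in [0, 1]
  m <- true_ptr^(1 - x)
  lambda <- mean_depth * m / mean(m)
  depth <- if (noise == "poisson") stats::rpois(genome_length, lambda)
           else lambda
  starts <- cumsum(c(1L, contig_lengths[-length(contig_lengths)]))
  ends <- starts + contig_lengths - 1L
  ids <- paste0("contig_", seq_along(contig_lengths))
  tables <- lapply(seq_along(contig_lengths), function(k) {
    idx <- starts[k]:ends[k]
    data.frame(contig_id = ids[k],
               position = seq_along(idx),      # contig-local 1-based
               depth = depth[idx])
  })
  names(tables) <- ids
  truth <- data.frame(contig_id = ids, start = starts, end = ends,
                      true_ptr = true_ptr,
                      expected_span = vapply(seq_along(ids), function(k) {
                        lam <- lambda[starts[k]:ends[k]]
                        max(lam) / min(lam)
                      }, numeric(1)))
  list(depth = tables, truth = truth)
}

#' Assign simulated taxonomy labels to contigs
#'
#' Multinomial draw of phylum labels (including an unclassified mass,
#' represented as NA at the phylum rank) for a set of contigs.
#'
#' @param contig_ids Character vector of contig ids.
#' @param phyla Character vector of phylum names; use `NA` for the
#'   unclassified category.
#' @param proportions Probabilities matching `phyla`, summing to 1.
#' @param seed Optional integer seed.
#'
#' @return Data.frame `contig_id`, `superkingdom`, `phylum` (NA when
#'   unclassified), lower ranks left unclassified (`""`).
#' @export
simulate_taxa <- function(contig_ids, phyla, proportions, seed = NULL) {
  stopifnot(length(phyla) == length(proportions),
            abs(sum(proportions) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  lab <- sample(seq_along(phyla), length(contig_ids), replace = TRUE,
                prob = proportions)
  phylum <- phyla[lab]
  data.frame(contig_id = contig_ids,
             superkingdom = ifelse(is.na(phylum), "", "Bacteria"),
             phylum = phylum,
             class = "", order = "", family = "", genus = "")
}

#' Default per-feature specification table for cohort simulation
#'
#' Helper building the `feature_specs` data.frame consumed by
#' [simulate_cohort()]: `n` features of one kind sharing effect sizes.
#'
#' @param n Number of features.
#' @param kind `"continuous_log"`, `"ordinal"` or `"count"`.
#' @param beta_bmi Effect of baseline BMI (per kg/m^2, model scale).
#' @param beta_wl Effect of weight-loss group membership (model scale;
#'   natural-log fold change for counts).
#' @param beta_sex Effect of sex (model scale).
#' @param noise_sd Residual SD on the model scale (continuous/ordinal).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2) for
#'   counts.
#' @param prefix Feature-id prefix.
#' @return Data.frame of per-feature specs.
#' @export
feature_spec <- function(n, kind, beta_bmi = 0, beta_wl = 0, beta_sex = 0,
                         noise_sd = 0.5, dispersion = 0.1,
                         prefix = kind) {
  data.frame(feature_id = sprintf("%s_%03d", prefix, seq_len(n)),
             kind = kind, beta_bmi = beta_bmi, beta_wl = beta_wl,
             beta_sex = beta_sex, noise_sd = noise_sd,
             dispersion = dispersion)
}

#' Simulate a weight-loss cohort with known effect structure
#'
#' Generates subject metadata (baseline BMI and age normal, sex Bernoulli
#' 0.5, weight-loss group by `group_fraction`) and one feature matrix per
#' requested kind. Continuous features are Gaussian on the log scale with
#' linear BMI/group/sex effects; count features have NB-distributed counts
#' whose mean is a per-sample library-size factor times the exponentiated
#' linear predictor; ordinal features discretize a latent Gaussian with the
#' same predictor into the 0-8 scale at equal quantiles. BMI and age enter
#' the predictor centered at their simulation means, so recovered
#' coefficients equal the specified betas.
#'
#' @param n_subjects Number of subjects (default 105, with the metagenomic
#'   assays typically run on a 25-subject subset).
#' @param group_fraction Fraction assigned to the weight-loss group
#'   (default 48/105).
#' @param bmi_mean,bmi_sd Baseline BMI distribution (default 29, 5 kg/m^2).
#' @param age_mean,age_sd Age distribution (default 48, 12 years).
#' @param feature_specs Data.frame from [feature_spec()] (rows may mix
#'   kinds); `NULL` generates no features.
#' @param library_size_range Range of per-sample library-size factors for
#'   count features (default `c(0.5, 2)`, log-uniform).
#' @param intercepts Named list of per-kind intercepts on the model scale
#'   (defaults: continuous_log 2, count log(200), ordinal 0).
#' @param seed Optional integer seed; fixed seed gives identical output.
#'
#' @return List with `meta` (data.frame `subject_id`, `sex`, `age`,
#'   `baseline_bmi`, `baseline_weight`, `followup_weight`, `months_between`,
#'   `group`; the weight trajectory is drawn consistently with the group
#'   label, so re-deriving groups from the weights reproduces them),
#'   `features` (named list of `feature_matrix` objects, one per kind
#'   present), `size_factors` (true library-size factors used for counts),
#'   and `truth` (data.frame `feature_id`, `term`, `true_beta` for every
#'   nonzero effect).
#' @export
simulate_cohort <- function(n_subjects = 105, group_fraction = 48 / 105,
                            bmi_mean = 29, bmi_sd = 5,
                            age_mean = 48, age_sd = 12,
                            feature_specs = NULL,
                            library_size_range = c(0.5, 2),
                            intercepts = list(continuous_log = 2,
                                              count = log(200),
                                              ordinal = 0),
                            seed = NULL) {
  stopifnot(group_fraction > 0, group_fraction < 1, bmi_sd > 0, age_sd > 0)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  n_wl <- round(group_fraction * n_subjects)
  group <- sample(rep(c("weight_loss", "no_weight_loss"),
                      c(n_wl, n_subjects - n_wl)))
  bmi <- stats::rnorm(n_subjects, bmi_mean, bmi_sd)
  height <- stats::rnorm(n_subjects, 1.70, 0.09)
  baseline_weight <- bmi * height^2
  months <- stats::runif(n_subjects, 6, 12)
  wl <- group == "weight_loss"
  rate <- ifelse(wl, stats::runif(n_subjects, -3, -1.05),
                 stats::runif(n_subjects, 0, 0.095))
  meta <- data.frame(subject_id = ids,
                     sex = sample(c("female", "male"), n_subjects,
                                  replace = TRUE),
                     age = stats::rnorm(n_subjects, age_mean, age_sd),
                     baseline_bmi = bmi,
                     baseline_weight = baseline_weight,
                     followup_weight = baseline_weight *
                       (1 + rate / 100 * months),
                     months_between = months,
                     group = group)
  sf <- exp(stats::runif(n_subjects, log(library_size_range[1]),
                         log(library_size_range[2])))
  names(sf) <- ids
  features <- list()
  truth <- data.frame(feature_id = character(0), term = character(0),
                      true_beta = numeric(0))
  if (!is.null(feature_specs) && nrow(feature_specs) > 0) {
    bmi_c <- meta$baseline_bmi - bmi_mean
    age_c <- meta$age - age_mean
    g <- as.integer(meta$group == "weight_loss")
    sx <- as.integer(meta$sex == "male")
    for (kd in intersect(c("continuous_log", "ordinal", "count"),
                         unique(feature_specs$kind))) {
      sp <- feature_specs[feature_specs$kind == kd, , drop = FALSE]
      vals <- matrix(0, nrow(sp), n_subjects,
                     dimnames = list(sp$feature_id, ids))
      for (i in seq_len(nrow(sp))) {
        eta <- intercepts[[kd]] + sp$beta_bmi[i] * bmi_c +
          sp$beta_wl[i] * g + sp$beta_sex[i] * sx
        vals[i, ] <- switch(kd,
          continuous_log = eta + stats::rnorm(n_subjects, 0,
                                              sp$noise_sd[i]),
          count = stats::rnbinom(n_subjects,
                                 mu = sf * exp(eta),
                                 size = 1 / sp$dispersion[i]),
          ordinal = {
            latent <- eta + stats::rnorm(n_subjects, 0, sp$noise_sd[i])
            cuts <- stats::quantile(latent, probs = seq(1 / 9, 8 / 9,
                                                        by = 1 / 9))
            findInterval(latent, cuts)
          })
      }
      features[[kd]] <- feature_matrix(vals, kind = kd)
      for (term in c("beta_bmi", "beta_wl", "beta_sex")) {
        nz <- sp[[term]] != 0
        if (any(nz)) {
          truth <- rbind(truth,
                         data.frame(feature_id = sp$feature_id[nz],
                                    term = sub("beta_", "", term),
                                    true_beta = sp[[term]][nz]))
        }
      }
    }
  }
  list(meta = meta, features = features, size_factors = sf, truth = truth)
}
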