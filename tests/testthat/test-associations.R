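test_that("design matrices carry the right target and catch collinearity", {
  meta <- toy_meta(12)
  d_wl <- model_design(meta, "weight_loss")
  expect_equal(colnames(d_wl$design),
               c("(Intercept)", "group", "baseline_bmi", "age", "sex"))
  expect_equal(d_wl$target_term, "group")
  d_bmi <- model_design(meta, "baseline_bmi")
  expect_false("group" %in% colnames(d_bmi$design))

  meta$age <- meta$baseline_bmi   # linearly dependent columns
  expect_error(model_design(meta, "weight_loss"), "collinear")
})

test_that("per-feature OLS matches the textbook simple-regression closed form", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 11.9)
  design <- cbind(`(Intercept)` = 1, x = x)
  fm <- feature_matrix(matrix(y, 1, 6, dimnames = list("f", paste0("s", 1:6))),
                       "continuous_log")
  fit <- fit_gaussian(fm, design, target_term = "x")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) - slope * mean(x)) - slope * x
  se <- sqrt(sum(resid^2) / 4 / sxx)
  expect_equal(fit$coef, slope, tolerance = 1e-12)
  expect_equal(fit$se, se, tolerance = 1e-12)
  expect_equal(fit$t, slope / se, tolerance = 1e-12)
  expect_equal(fit$p, 2 * pt(-abs(slope / se), 4), tolerance = 1e-12)
})

test_that("constant features are flagged instead of reported significant", {
  meta <- toy_meta(16)
  m <- matrix(c(rep(3.5, 16), rnorm(16)), 2, 16, byrow = TRUE,
              dimnames = list(c("flat", "noisy"), meta$subject_id))
  fit <- fit_gaussian(feature_matrix(m, "continuous_log"),
                      model_design(meta, "weight_loss"))
  expect_true(fit$zero_variance[fit$feature_id == "flat"])
  expect_equal(fit$coef[fit$feature_id == "flat"], 0)
  expect_true(is.na(fit$p[fit$feature_id == "flat"]))
  expect_false(fit$zero_variance[fit$feature_id == "noisy"])
})

test_that("OLS recovers a known group effect", {
  set.seed(14)
  meta <- toy_meta(100)
  g <- as.integer(meta$group == "weight_loss")
  y <- 2 * g + rnorm(100, 0, 0.1)
  fm <- feature_matrix(matrix(y, 1, 100,
                              dimnames = list("f", meta$subject_id)),
                       "continuous_log")
  fit <- fit_gaussian(fm, model_design(meta, "weight_loss"))
  expect_gt(fit$coef, 1.9)
  expect_lt(fit$coef, 2.1)
  expect_lt(fit$p, 1e-10)
})

test_that("NB regression converges to Poisson regression as dispersion vanishes", {
  set.seed(6)
  n <- 100
  meta <- toy_meta(n)
  des <- model_design(meta, "weight_loss")
  g <- des$design[, "group"]
  y <- rpois(n, exp(3 + 0.6 * g))
  counts <- feature_matrix(matrix(y, 1, n,
                                  dimnames = list("f", meta$subject_id)),
                           "count")
  sf <- setNames(rep(1, n), meta$subject_id)
  nb <- fit_negative_binomial(counts, sf, des)
  dat <- as.data.frame(des$design[, -1])
  pois <- glm(y ~ group + baseline_bmi + age + sex, data = dat,
              family = poisson())
  expect_equal(nb$coef, unname(coef(pois)["group"]), tolerance = 1e-3)
})

test_that("NB regression respects the size-factor offset", {
  set.seed(26)
  n <- 60
  meta <- toy_meta(n)
  des <- model_design(meta, "weight_loss")
  sf <- setNames(exp(runif(n, -1, 1)), meta$subject_id)
  g <- des$design[, "group"]
  y <- rnbinom(n, mu = sf * exp(4 + 0.7 * g), size = 10)
  counts <- feature_matrix(matrix(y, 1, n,
                                  dimnames = list("f", meta$subject_id)),
                           "count")
  fit <- fit_negative_binomial(counts, sf, des)
  expect_equal(fit$coef, 0.7, tolerance = 0.25)
  expect_equal(fit$status, "ok")
})

test_that("all-zero count features are skipped with a reason", {
  meta <- toy_meta(10)
  m <- matrix(c(rep(0L, 10), rpois(10, 20)), 2, 10, byrow = TRUE,
              dimnames = list(c("zero", "ok"), meta$subject_id))
  sf <- setNames(rep(1, 10), meta$subject_id)
  fit <- fit_negative_binomial(feature_matrix(m, "count"), sf,
                               model_design(meta, "weight_loss"))
  expect_equal(fit$status, c("all_zero", "ok"))
  expect_true(is.na(fit$p[1]))
})

test_that("BH adjustment matches the step-up formula and its guarantees", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.04), 0.04)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  p <- runif(50)^2
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

test_that("dual-model classification follows the significance pattern", {
  expect_equal(classify_features(0.01, 0.50), "bmi_only")
  expect_equal(classify_features(0.50, 0.01), "wl_only")
  expect_equal(classify_features(0.01, 0.01), "both")
  expect_equal(classify_features(0.50, 0.50), "neither")
  expect_equal(classify_features(c(0.01, NA), c(NA, 0.2)),
               c("bmi_only", "neither"))
})

test_that("t-statistic correlation matches the product-moment closed form", {
  expect_equal(correlate_tstats(1:5, 1:5)$rho, 1)
  expect_equal(correlate_tstats(1:5, -(1:5))$rho, -1)
  set.seed(33)
  a <- rnorm(10)
  b <- 0.5 * a + rnorm(10)
  res <- correlate_tstats(a, b)
  rho <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tt <- rho * sqrt(8) / sqrt(1 - rho^2)
  expect_equal(res$rho, rho, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(tt), 8), tolerance = 1e-12)
  expect_equal(correlate_tstats(rep(1, 5), 1:5)$flag, "zero_variance")
})

test_that("reported t statistics equal coef/se and fdr never drops below p", {
  set.seed(41)
  meta <- toy_meta(40)
  fm <- toy_fm(25, 40, seed = 42)
  colnames(fm) <- meta$subject_id
  res <- associate_features(fm, meta)
  expect_equal(res$t_wl, res$coef_wl / res$se_wl)
  expect_equal(res$t_bmi, res$coef_bmi / res$se_bmi)
  expect_true(all(res$fdr_wl >= res$p_wl))
  expect_true(all(res$fdr_bmi >= res$p_bmi))
  expect_false(is.null(attr(res, "t_correlation")))
})

test_that("t and p are invariant to affine rescaling of the target covariate", {
  set.seed(44)
  meta <- toy_meta(40)
  fm <- toy_fm(10, 40, seed = 45)
  colnames(fm) <- meta$subject_id
  res1 <- associate_features(fm, meta)
  meta2 <- meta
  meta2$baseline_bmi <- 2 * meta$baseline_bmi + 5
  res2 <- associate_features(fm, meta2)
  expect_equal(res2$t_bmi, res1$t_bmi, tolerance = 1e-9)
  expect_equal(res2$p_bmi, res1$p_bmi, tolerance = 1e-9)
  expect_equal(res2$coef_bmi, res1$coef_bmi / 2, tolerance = 1e-9)
})

test_that("SRM change model finds nothing under the null and after permutation", {
  set.seed(51)
  meta <- toy_meta(25)
  null_d <- toy_fm(22, 25, seed = 52)
  colnames(null_d) <- meta$subject_id
  res_null <- srm_change_model(null_d, meta)
  expect_lte(sum(res_null$significant), 2)

  # real group shift in 7 proteins, destroyed by permuting labels
  g <- as.integer(meta$group == "weight_loss")
  shifted <- unclass(null_d)
  shifted[1:7, ] <- shifted[1:7, ] + log(2) * rep(g, each = 7) * 3
  d_eff <- feature_matrix(shifted, "continuous_log")
  res_eff <- srm_change_model(d_eff, meta)
  expect_gte(sum(res_eff$significant[1:7]), 5)
  perm_counts <- replicate(20, {
    pm <- meta
    pm$group <- sample(pm$group)
    sum(srm_change_model(d_eff, pm)$significant)
  })
  expect_lte(median(perm_counts), 1)
})

test_that("richness models recover a known BMI slope and flag constants", {
  set.seed(61)
  meta <- toy_meta(105)
  rich <- setNames(3000 - 19 * meta$baseline_bmi + rnorm(105, 0, 100),
                   meta$subject_id)
  rep1 <- richness_models(rich, meta)
  bmi_row <- rep1[rep1$model == "richness_vs_bmi" &
                    rep1$term == "baseline_bmi", ]
  expect_gt(bmi_row$estimate, -25)
  expect_lt(bmi_row$estimate, -13)

  flat <- richness_models(setNames(rep(100, 105), meta$subject_id), meta)
  expect_equal(unique(flat$flag), "zero_variance")
  expect_equal(unique(flat$estimate), 0)
})

test_that("Welch statistics match hand computation; self-correlation is 1", {
  meta <- data.frame(subject_id = c("a", "b", "c", "d"),
                     group = c("weight_loss", "weight_loss",
                               "no_weight_loss", "no_weight_loss"))
  m <- matrix(c(1, 2, 4, 7,
                1, 2, 3, 4), 2, 4, byrow = TRUE,
              dimnames = list(c("m1", "m2"), meta$subject_id))
  res <- baseline_group_tests(feature_matrix(m, "continuous_log"), meta)
  # Welch for m1: means 1.5 vs 5.5, variances 0.5 and 4.5
  tw <- (1.5 - 5.5) / sqrt(0.5 / 2 + 4.5 / 2)
  expect_equal(res$tests$t[res$tests$marker == "m1"], tw, tolerance = 1e-12)
  expect_equal(diag(res$cor), c(m1 = 1, m2 = 1))
  expect_equal(res$cor["m1", "m2"], cor(m[1, ], m[2, ]))
})

test_that("paired follow-up tests match a one-sample t on the differences", {
  set.seed(71)
  b <- toy_fm(3, 10, seed = 72)
  f <- feature_matrix(unclass(b) + rnorm(30, 0.3, 0.2), "continuous_log")
  res <- paired_followup_tests(b, f)
  for (i in 1:3) {
    dd <- unclass(f)[i, ] - unclass(b)[i, ]
    tt <- t.test(dd)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
})
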