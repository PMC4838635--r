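test_that("degrees-of-freedom algebra matches the study design", {
  k <- 6
  # full-pattern df for the baseline model: m^k - n - 1
  for (m in 2:4) {
    n0 <- study_model("baseline", k, m)$n_params
    expect_equal(m^k - n0 - 1, c(`2` = 42, `3` = 701, `4` = 4062)[[as.character(m)]])
  }
  # model-comparison df: 9 (one-factor) and 7 (two-factor), any m
  for (m in 2:4) {
    s1 <- study_model("one_factor", k, m)
    s2 <- study_model("two_factor", k, m)
    expect_equal(15 + k * (m - 1) - s1$n_params, 9)
    expect_equal(15 + k * (m - 1) - s2$n_params, 7)
  }
  # pairwise df m^2 - 2m and the Bonferroni level
  expect_equal(3^2 - 2 * 3, 3)
  expect_equal(4^2 - 2 * 4, 8)
  expect_equal(2 * 0.05 / (k * (k - 1)), 0.05 / 15)
})

test_that("chi-square p-values behave as an upper tail", {
  expect_equal(chisq_pvalue(0, 5), 1)
  expect_equal(chisq_pvalue(7.738, 7), 0.356, tolerance = 1e-3)
  expect_equal(chisq_pvalue(-2, 7), 1)   # negative statistic
  v <- seq(1, 40, by = 3)
  expect_true(all(diff(chisq_pvalue(v, 7)) < 0))
  expect_error(chisq_pvalue(1, 0), "df")
})

test_that("CF is zero at a perfect fit and uses both df conventions", {
  d <- tiny_data(n = 400, m = 2, seed = 19)
  # a fitted table equal to the observed proportions gives CF = 0
  fake <- structure(list(
    prob = rep(0, 64), patterns = pmlfa:::pattern_from_index(1:64, 2, 6),
    deficit = 0, m = 2L, k = 6L, renormalized = TRUE),
    class = "pattern_probs")
  fake$prob[d$pattern_index] <- d$pattern_counts / d$n
  cf <- compute_cf(d, fake, n_params = 21)
  expect_equal(cf$cf$value, 0)
  expect_equal(cf$cf$df, 64 - 21 - 1)
  expect_equal(cf$cf_star$df, length(d$pattern_counts) - 21 - 1)
  expect_identical(cf$cf$u_r, length(d$pattern_counts))
  expect_false(cf$cf$reject)
  # df* clamps at 1 with a warning when u_r - n - 1 <= 0 (here a small
  # sample where few patterns are observed but m^k - n - 1 stays valid)
  ds <- tiny_data(n = 30, m = 2, seed = 19)
  fake2 <- fake
  fake2$prob[] <- 1 / 64
  expect_warning(
    cf2 <- compute_cf(ds, fake2,
                      n_params = length(ds$pattern_counts) - 1),
    "clamped")
  expect_equal(cf2$cf_star$df, 1)
  expect_true("df_clamped" %in% cf2$cf_star$flags)
})

test_that("CM is the CF difference, with the negative case flagged not clamped", {
  spec1 <- study_model("one_factor", 6, 2)
  cm <- compute_cm(50, 30, spec1)
  expect_equal(cm$value, 20)
  expect_equal(cm$df, 9)
  expect_equal(cm$p_value, pchisq(20, 9, lower.tail = FALSE))
  # identical models: zero
  expect_equal(compute_cm(30, 30, spec1)$value, 0)
  # adversarial: the structured model beats the baseline on the full
  # patterns (possible because PML does not maximize them)
  cm_neg <- compute_cm(25, 30, spec1)
  expect_equal(cm_neg$value, -5)
  expect_true("negative_finite_sample" %in% cm_neg$flags)
  expect_equal(cm_neg$p_value, 1)
  expect_false(cm_neg$reject)
})

test_that("CF + CM additivity holds by construction on real fits", {
  d <- tiny_data(n = 300, m = 2, seed = 29)
  g <- suppressWarnings(pml_gof(d, "one_factor", statistics = c("CF", "CM")))
  cf0 <- suppressWarnings(
    compute_cf(d, fitted_pattern_probs(g$baseline_fit),
               g$baseline_fit$spec$n_params))
  expect_equal(cf0$cf$value + g$statistics$CM$value, g$statistics$CF$value,
               tolerance = 1e-6)
})

test_that("CP refuses dichotomous items and is calibrated in structure", {
  d2 <- tiny_data(n = 200, m = 2, seed = 37)
  f2 <- quiet_fit(d2, study_model("baseline", 6, 2))
  expect_error(compute_cp(d2, f2), "cannot be tested")

  d <- tiny_data(n = 400, m = 3, seed = 37)
  fit <- quiet_fit(d, study_model("baseline", 6, 3))
  cp <- compute_cp(d, fit)
  expect_equal(nrow(cp$pair_stats), 15)
  expect_equal(cp$overall$df, 3)
  expect_equal(cp$alpha_star, 0.05 / 15)
  expect_equal(cp$overall$value, max(cp$pair_stats$value))
  expect_true(all(cp$pair_stats$value >= 0))
  # the decision depends only on the maximum value
  expect_identical(cp$overall$reject,
                   chisq_pvalue(max(cp$pair_stats$value), 3) < cp$alpha_star)
  # perfect fit: every pairwise statistic is zero, nothing rejects
  dtoy <- dataset_from_table(matrix(25, 3, 3))
  # uniform 3x3 table: independence with uniform margins fits exactly
  ftoy <- quiet_fit(dtoy, fm_spec(2, 3, "baseline"))
  cptoy <- compute_cp(dtoy, ftoy)
  expect_lt(cptoy$overall$value, 1e-4)
  expect_false(cptoy$overall$reject)
})

test_that("gof wrapper assembles all applicable statistics", {
  d <- tiny_data(n = 250, m = 3, seed = 41)
  g <- suppressWarnings(pml_gof(d, "two_factor", statistics = c("CF", "CM", "CP"),
                                max_patterns = 64))
  # m^k = 729 > 64: full-pattern statistics are skipped with a note
  expect_null(g$statistics$CF)
  expect_match(g$skipped_cf, "max_patterns")
  expect_s3_class(g$statistics$CP, "cp_result")
  g2 <- suppressWarnings(pml_gof(tiny_data(n = 250, m = 2, seed = 41),
                                 "two_factor", statistics = c("CF", "CM")))
  expect_s3_class(g2$statistics$CF, "fit_statistic")
  expect_s3_class(g2$statistics$CM, "fit_statistic")
  expect_equal(g2$statistics$CM$df, 7)
})
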