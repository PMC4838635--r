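test_that("pattern probabilities factorize and agree with the bivariate kernel", {
  # identity correlation: product of univariate interval probabilities
  tau <- study_thresholds(3)
  p <- pattern_prob(diag(4), tau, c(1, 2, 3, 2))
  marg <- diff(pnorm(c(-Inf, tau, Inf)))
  expect_equal(p, marg[1] * marg[2] * marg[3] * marg[2], tolerance = 1e-6)

  # k = 2: cross-module agreement with the vectorized bivariate engine
  R2 <- matrix(c(1, 0.72, 0.72, 1), 2)
  for (a in 1:3) for (b in 1:3)
    expect_lt(abs(pattern_prob(R2, tau, c(a, b)) -
                    bivariate_cell_prob(0.72, tau, tau, a, b)), 1e-6)
  expect_error(pattern_prob(matrix(c(1, 1, 1, 1), 2), tau, c(1, 1)),
               "positive definite")
})

test_that("frozen simulation oracle: all-ones pattern under the population model", {
  # quasi-random brute force with 1e7 latent draws gave 0.137979
  # (MC SE 0.000109); the integral must fall within 3 MC SEs
  p <- pattern_prob(pop_sigma(), study_thresholds(2), rep(1, 6))
  expect_equal(p, 0.137979, tolerance = 3 * 0.000109 / 0.137979)
})

test_that("the full m^k table is complete, normalized, and marginalizes", {
  ap <- all_pattern_probs(pop_sigma(), study_thresholds(2), m = 2,
                          renormalize = FALSE)
  expect_length(ap$prob, 64)
  expect_lt(abs(ap$deficit), 1e-4)
  expect_true(all(ap$prob >= 0 & ap$prob <= 1))

  # identity correlation: every pattern equals the product of marginals
  ap0 <- all_pattern_probs(diag(3), study_thresholds(3), m = 3)
  marg <- diff(pnorm(c(-Inf, study_thresholds(3), Inf)))
  expected <- apply(ap0$patterns, 1, function(r) prod(marg[r]))
  expect_equal(ap0$prob, expected, tolerance = 1e-5)

  # marginalizing the table over all other items reproduces the
  # bivariate cell probabilities
  S <- pop_sigma()[1:3, 1:3]
  ap3 <- all_pattern_probs(S, study_thresholds(3), m = 3,
                           renormalize = FALSE)
  for (a in 1:3) for (b in 1:3) {
    mass <- sum(ap3$prob[ap3$patterns[, 1] == a & ap3$patterns[, 2] == b])
    expect_lt(abs(mass - bivariate_cell_prob(S[1, 2], study_thresholds(3),
                                             study_thresholds(3), a, b)),
              2e-5)
  }
  expect_error(all_pattern_probs(diag(6), study_thresholds(4), m = 4,
                                 max_patterns = 1000),
               "ceiling")
})

test_that("pattern probabilities are invariant under item permutation", {
  S <- pop_sigma()[1:4, 1:4]
  tau <- matrix(study_thresholds(3), 4, 2, byrow = TRUE)
  pat <- c(1, 3, 2, 2)
  perm <- c(3, 1, 4, 2)
  p1 <- pattern_prob(S, tau, pat)
  p2 <- pattern_prob(S[perm, perm], tau[perm, ], pat[perm])
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("observed-pattern lookup aligns with the dataset encoding", {
  d <- tiny_data(n = 200, m = 2, seed = 9)
  ap <- all_pattern_probs(pop_sigma(), study_thresholds(2), m = 2)
  pr <- observed_pattern_probs(ap, d)
  expect_length(pr, length(d$pattern_counts))
  # recompute one pattern directly
  r <- which.max(d$pattern_counts)
  expect_equal(pr[r], pattern_prob(pop_sigma(), study_thresholds(2),
                                   d$patterns[r, ]),
               tolerance = 1e-5)
})
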