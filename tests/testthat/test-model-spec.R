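test_that("study models carry the correct free-parameter counts", {
  # one-factor, m = 2: 6 loadings + 6 thresholds
  s1 <- study_model("one_factor", 6, 2)
  expect_identical(s1$n_params, 12L)
  # baseline: k(k-1)/2 polychorics + k(m-1) thresholds
  for (m in 2:4) {
    s0 <- study_model("baseline", 6, m)
    expect_identical(s0$n_params, as.integer(15 + 6 * (m - 1)))
  }
  # two-factor: 7 loadings + 1 factor correlation, any m
  for (m in 2:4) {
    s2 <- study_model("two_factor", 6, m)
    expect_identical(s2$n_structural, 8L)
  }
  expect_error(study_model("three_factor"), "arg")
  expect_error(study_model("two_factor", k = 5, m = 2), "k = 6")
})

test_that("implied correlations reproduce the population matrix", {
  spec <- study_model("two_factor", 6, 2)
  S <- suppressWarnings(
    implied_correlations(spec, population_loadings(), population_phi()))
  expect_equal(S[1, 2], 0.9 * 0.8, tolerance = 1e-12)          # both on f1
  expect_equal(S[3, 4], 0.7 * 0.5 * 0.6 + 0.5 * 0.6, tolerance = 1e-12)
  expect_true(isSymmetric(S))
  expect_equal(diag(S), rep(1, 6))
  # item 3's communality exceeds 1: flagged as improper, not an error
  expect_warning(implied_correlations(spec, population_loadings(),
                                      population_phi()),
                 "communality")
  # all loadings zero: independence
  spec1 <- study_model("one_factor", 6, 3)
  expect_equal(implied_correlations(spec1, matrix(0, 6, 1), diag(1)),
               diag(6))
  # loadings outside the pattern are rejected
  L_bad <- population_loadings(); L_bad[1, 2] <- 0.3
  expect_error(implied_correlations(spec, L_bad, population_phi()),
               "outside")
})

test_that("implied correlations are invariant under factor sign flips", {
  spec <- study_model("two_factor", 6, 2)
  set.seed(11)
  for (rep in 1:10) {
    L <- ifelse(spec$loading_mask, runif(12, -0.7, 0.7), 0)
    phi <- matrix(c(1, runif(1, -0.8, 0.8)), 2, 2)[c(1, 2, 2, 1)]
    phi <- matrix(phi, 2)
    S <- suppressWarnings(implied_correlations(spec, L, phi))
    s <- sample(c(-1, 1), 2, replace = TRUE)
    Lf <- sweep(L, 2, s, `*`)
    phif <- diag(s) %*% phi %*% diag(s)
    Sf <- suppressWarnings(implied_correlations(spec, Lf, phif))
    expect_equal(S, Sf, tolerance = 1e-12)
  }
})

test_that("parameter pack/unpack round-trips for every study model", {
  for (mod in c("baseline", "one_factor", "two_factor"))
    for (m in 2:3) {
      spec <- study_model(mod, 6, m)
      tau <- matrix(seq(-1, 1, length.out = m - 1), 6, m - 1, byrow = TRUE)
      if (mod == "baseline") {
        rho <- seq(-0.4, 0.6, length.out = 15)
        p <- pack_params(spec, tau, rho = rho)
        expect_identical(length(p), spec$n_params)
        expect_identical(names(p), param_names(spec))
        u <- unpack_params(spec, p)
        expect_equal(u$thresholds, tau)
        expect_equal(u$rho, rho)
        expect_equal(u$rho_matrix[t(spec$pairs)], rho)
      } else {
        L <- ifelse(spec$loading_mask, 0.5, 0)
        phi <- if (spec$q == 2) matrix(c(1, .3, .3, 1), 2) else diag(1)
        p <- pack_params(spec, tau, loadings = L, phi = phi)
        u <- unpack_params(spec, p)
        expect_equal(u$thresholds, tau)
        expect_equal(u$loadings, L)
        expect_equal(u$phi, phi)
      }
    }
  # invalid inputs are refused
  spec <- study_model("baseline", 6, 2)
  expect_error(pack_params(spec, matrix(0, 6, 1), rho = rep(1.2, 15)),
               "\\(-1, 1\\)")
  expect_error(pack_params(study_model("baseline", 6, 3),
                           matrix(c(0.5, -0.5), 6, 2), rho = rep(0, 15)),
               "increasing")
})
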