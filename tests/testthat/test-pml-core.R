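test_that("bivariate cell probabilities are coherent and match quadrature", {
  # independence with median splits: all four cells are 1/4
  expect_equal(bivariate_cell_prob(0, 0, 0, c(1, 1, 2, 2), c(1, 2, 1, 2)),
               rep(0.25, 4))
  # independence factorizes for arbitrary thresholds
  ti <- c(-0.8, 0.4); tj <- c(-1.1, 0.9)
  for (a in 1:3) for (b in 1:3) {
    pa <- diff(pnorm(c(-Inf, ti, Inf)))[a]
    pb <- diff(pnorm(c(-Inf, tj, Inf)))[b]
    expect_equal(bivariate_cell_prob(0, ti, tj, a, b), pa * pb,
                 tolerance = 1e-12)
  }
  # frozen oracle: 2-D adaptive quadrature of the bivariate density over
  # (-Inf, -0.6]^2 at rho = 0.72 gives 0.173238753256 (abs err < 1e-11)
  expect_equal(bivariate_cell_prob(0.72, c(-0.6, 0.6), c(-0.6, 0.6), 1, 1),
               0.173238753256, tolerance = 1e-8)
  # cells of a pair sum to one
  for (m in 2:4) {
    tau <- study_thresholds(m)
    P <- pair_cell_probs(0.6, tau, tau)
    expect_equal(sum(P), 1, tolerance = 1e-10)
    expect_true(all(P > 0))
  }
  expect_error(bivariate_cell_prob(1, 0, 0, 1, 1), "invalid")
  expect_error(bivariate_cell_prob(0.5, 0, 0, 3, 1), "range")
})

test_that("pairwise log-likelihood matches hand computation and Gibbs bound", {
  # 2-item toy table at independence with median splits: every cell
  # probability is 1/4, so the objective is 100 * ln(1/4)
  d <- dataset_from_table(matrix(c(30, 20, 10, 40), 2, byrow = TRUE))
  spec <- fm_spec(2, 2, "baseline")
  p <- pack_params(spec, matrix(0, 2, 1), rho = 0)
  expect_equal(pairwise_loglik(d, p, spec), 100 * log(0.25),
               tolerance = 1e-10)
  expect_equal(100 * log(0.25), -138.629, tolerance = 1e-3)

  # Gibbs inequality: no parameter value beats the observed proportions
  attainable <- sum(d$pair_tables[, , 1] * log(d$pair_tables[, , 1] / d$n))
  for (r in c(-0.5, 0, 0.3, 0.8)) {
    p2 <- pack_params(spec, matrix(0.2, 2, 1), rho = r)
    expect_lte(pairwise_loglik(d, p2, spec), attainable + 1e-9)
  }
})

test_that("analytic gradients match numerical differentiation", {
  skip_if_not_installed("numDeriv")
  d <- tiny_data(n = 400, m = 3, seed = 13)
  for (mod in c("baseline", "two_factor")) {
    spec <- study_model(mod, 6, 3)
    ctx <- pmlfa:::pml_context(spec, d)
    set.seed(17)
    tau <- t(replicate(6, sort(runif(2, -1, 1))))
    rho <- runif(15, -0.6, 0.6)
    ev <- pmlfa:::pml_eval(ctx, tau, rho, want_grad = TRUE)
    g <- c(as.vector(t(ev$g_tau)), ev$g_rho)
    f <- function(v) pmlfa:::pml_eval(ctx, matrix(v[1:12], 6, byrow = TRUE),
                                      v[13:27], want_grad = FALSE)$obj
    g_num <- numDeriv::grad(f, c(as.vector(t(tau)), rho))
    expect_lt(max(abs(g - g_num) / (abs(g_num) + 1e-6)), 1e-4)
  }
})

test_that("k = 2 PML equals the classical one-step polychoric estimate", {
  # independent oracle: direct maximization of the bivariate multinomial
  # likelihood with mvtnorm(Miwa) cell probabilities over (tau_i, tau_j, rho)
  d <- dataset_from_table(matrix(c(55, 20, 15, 60), 2, byrow = TRUE))
  spec <- fm_spec(2, 2, "baseline")
  fit <- fit_pml(d, spec)
  tab <- d$pair_tables[, , 1]
  nll <- function(v) {
    C <- function(a, b) mvtnorm::pmvnorm(
      upper = c(a, b), corr = matrix(c(1, v[3], v[3], 1), 2),
      algorithm = mvtnorm::Miwa(steps = 256))
    p11 <- C(v[1], v[2])
    p1. <- pnorm(v[1]); p.1 <- pnorm(v[2])
    P <- matrix(c(p11, p.1 - p11, p1. - p11, 1 - p1. - p.1 + p11), 2)
    -sum(tab * log(P))
  }
  o <- optim(c(0, 0, 0.5), nll, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$rho, o$par[3], tolerance = 1e-4)
  expect_equal(as.vector(fit$thresholds), o$par[1:2], tolerance = 1e-4)
})

test_that("fits are invariant under strictly increasing relabelings", {
  d <- tiny_data(n = 300, m = 3, seed = 23)
  spec <- study_model("one_factor", 6, 3)
  f1 <- quiet_fit(d, spec)
  # relabel categories 1,2,3 -> 2,5,9, then canonicalize back to ranks
  relabeled <- matrix(c(2L, 5L, 9L)[d$codes], nrow(d$codes))
  d2 <- ordinal_data(canonicalize_codes(relabeled), m = 3)
  f2 <- quiet_fit(d2, spec)
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-8)
  expect_equal(f1$thresholds, f2$thresholds, tolerance = 1e-8)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
})

test_that("nested models are ordered by objective value", {
  for (seed in c(31, 32)) {
    d <- tiny_data(n = 250, m = 3, seed = seed)
    f0 <- quiet_fit(d, study_model("baseline", 6, 3))
    f2 <- quiet_fit(d, study_model("two_factor", 6, 3))
    f1 <- quiet_fit(d, study_model("one_factor", 6, 3))
    expect_gte(f0$objective, f2$objective - 1e-6)
    expect_gte(f2$objective, f1$objective - 1e-6)
  }
})

test_that("two-factor estimates recover the population parameters", {
  # moderate-scale recovery check; the full unbiasedness property is
  # exercised at replication scale by the harness tests
  set.seed(1)
  est <- t(sapply(1:25, function(r) {
    d <- simulate_ordinal(generation_config(1000, 3, seed = 500 + r))
    f <- quiet_fit(d, study_model("two_factor", 6, 3))
    al <- pmlfa:::align_two_factor(f)
    c(al$loadings, al$phi)
  }))
  truth <- c(population_loadings()[study_model("two_factor", 6, 3)$loading_mask],
             0.5)
  bias <- colMeans(est) - truth
  mcse <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 3 * mcse + 0.01))
})

test_that("an empty boundary category pins its threshold and flags the fit", {
  # force an empty top category on item 1
  d <- tiny_data(n = 120, m = 3, seed = 3)
  codes <- d$codes
  codes[codes[, 1] == 3, 1] <- 2L
  d2 <- ordinal_data(codes, m = 3)
  expect_warning(f <- fit_pml(d2, study_model("baseline", 6, 3)),
                 "pinned")
  expect_true("empty_category" %in% f$flags)
  expect_equal(f$thresholds[1, 2], 6)
})
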