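#' Bivariate cell probability under the underlying-normal model
#'
#' Probability that two items with latent correlation \code{rho} and
#' thresholds \code{tau_i}, \code{tau_j} produce the response pair
#' \code{(x_i, x_j)}: the standard bivariate normal measure of the
#' rectangle between consecutive thresholds, computed as a double
#' difference of four CDF values.  Vectorized over \code{x_i, x_j}.
#'
#' @param rho latent correlation, \eqn{|\rho| < 1}.
#' @param tau_i,tau_j numeric vectors of \eqn{m - 1} strictly increasing
#'   thresholds.
#' @param x_i,x_j integer categories in 1..m.
#' @return numeric vector of probabilities; over all \eqn{m^2} cells of
#'   a pair the probabilities sum to 1.
#' @export
bivariate_cell_prob <- function(rho, tau_i, tau_j, x_i, x_j) {
  if (any(abs(rho) >= 1)) stop("invalid parameter: |rho| must be < 1")
  ti <- c(-Inf, tau_i, Inf)
  tj <- c(-Inf, tau_j, Inf)
  if (any(x_i < 1L | x_i > length(tau_i) + 1L) ||
      any(x_j < 1L | x_j > length(tau_j) + 1L))
    stop("category out of range")
  pbvnorm(ti[x_i + 1L], tj[x_j + 1L], rho) -
    pbvnorm(ti[x_i],      tj[x_j + 1L], rho) -
    pbvnorm(ti[x_i + 1L], tj[x_j],      rho) +
    pbvnorm(ti[x_i],      tj[x_j],      rho)
}

#' All m x m cell probabilities for one item pair
#'
#' @inheritParams bivariate_cell_prob
#' @return \code{m x m} matrix of cell probabilities (rows: categories
#'   of item i).
#' @export
pair_cell_probs <- function(rho, tau_i, tau_j) {
  if (abs(rho) >= 1) stop("invalid parameter: |rho| must be < 1")
  m <- length(tau_i) + 1L
  ti <- c(-Inf, tau_i, Inf)
  tj <- c(-Inf, tau_j, Inf)
  C <- matrix(pbvnorm(rep(ti, times = m + 1L), rep(tj, each = m + 1L), rho),
              m + 1L, m + 1L)
  C[-1L, -1L] - C[-(m + 1L), -1L] - C[-1L, -(m + 1L)] + C[-(m + 1L), -(m + 1L)]
}

#' Pairwise log-likelihood of an ordinal dataset
#'
#' The PML objective: \eqn{N \sum_{i<j} \sum_{x_i} \sum_{x_j}
#' p_{x_i x_j} \ln \pi_{x_i x_j}}, where \eqn{p} are observed pairwise
#' proportions and \eqn{\pi} the model-implied bivariate cell
#' probabilities.  The multinomial constant is dropped (consistently for
#' all models, so likelihood differences are unaffected); cells with
#' zero observed count contribute nothing.  Model probabilities are
#' floored at \code{prob_floor} inside the logarithm; a warning is
#' emitted if a floored cell carries observed mass.
#'
#' @param dataset an [ordinal_data()] object.
#' @param params packed parameter vector ([pack_params()]) or the list
#'   produced by [unpack_params()].
#' @param spec the [fm_spec()] the parameters belong to.
#' @param prob_floor lower clip for model cell probabilities.
#' @return the scalar objective value (scaled by \eqn{N}).
#' @export
pairwise_loglik <- function(dataset, params, spec, prob_floor = 1e-12) {
  stopifnot(inherits(dataset, "ordinal_data"), inherits(spec, "fm_spec"))
  if (!is.list(params)) params <- unpack_params(spec, params)
  ctx <- pml_context(spec, dataset)
  ev <- pml_eval(ctx, params$thresholds, params$rho, want_grad = FALSE,
                 prob_floor = prob_floor)
  if (ev$n_floored > 0L)
    warning(ev$n_floored, " observed cell(s) had model probability below ",
            "the floor ", prob_floor)
  dataset$n * ev$obj
}

# precomputed fitting context: observed pairwise proportions and layout
pml_context <- function(spec, dataset) {
  if (dataset$m != spec$m || dataset$k != spec$k)
    stop("dataset dimensions inconsistent with the model spec")
  list(k = spec$k, m = spec$m, K = ncol(spec$pairs), pairs = spec$pairs,
       n = dataset$n, pobs = dataset$pair_tables / dataset$n)
}

# Objective (per-observation scale) and analytic gradient of the
# pairwise log-likelihood in the natural parameters (tau, rho).
pml_eval <- function(ctx, tau, rho, want_grad = TRUE, prob_floor = 1e-12) {
  m <- ctx$m; K <- ctx$K
  obj <- 0
  n_floored <- 0L
  g_tau <- if (want_grad) matrix(0, ctx$k, m - 1L) else NULL
  g_rho <- if (want_grad) numeric(K) else NULL
  for (p in seq_len(K)) {
    i <- ctx$pairs[1L, p]; j <- ctx$pairs[2L, p]
    r <- rho[p]
    ti <- c(-Inf, tau[i, ], Inf)
    tj <- c(-Inf, tau[j, ], Inf)
    C <- matrix(pbvnorm(rep(ti, times = m + 1L), rep(tj, each = m + 1L), r),
                m + 1L, m + 1L)
    P <- C[-1L, -1L] - C[-(m + 1L), -1L] - C[-1L, -(m + 1L)] +
         C[-(m + 1L), -(m + 1L)]
    W <- ctx$pobs[, , p]
    pos <- W > 0
    n_floored <- n_floored + sum(pos & P < prob_floor)
    Pf <- pmax(P, prob_floor)
    obj <- obj + sum(W[pos] * log(Pf[pos]))
    if (!want_grad) next
    Wq <- matrix(0, m, m)
    Wq[pos] <- W[pos] / Pf[pos]
    # d pi / d rho: double difference of the bivariate density grid
    D <- matrix(dbvnorm(rep(ti, times = m + 1L), rep(tj, each = m + 1L), r),
                m + 1L, m + 1L)
    dP <- D[-1L, -1L] - D[-(m + 1L), -1L] - D[-1L, -(m + 1L)] +
          D[-(m + 1L), -(m + 1L)]
    g_rho[p] <- sum(Wq * dP)
    s <- sqrt(1 - r^2)
    # thresholds of item i: U[a, b] = phi(tau_ia) * P(x_j = b | x_i* = tau_ia)
    Ti <- tau[i, ]; Tj <- tau[j, ]
    cnd <- pnorm((matrix(tj, m - 1L, m + 1L, byrow = TRUE) -
                    r * Ti) / s)              # (m-1) x (m+1)
    U <- dnorm(Ti) * (cnd[, -1L, drop = FALSE] - cnd[, -(m + 1L), drop = FALSE])
    g_tau[i, ] <- g_tau[i, ] +
      rowSums((Wq[-m, , drop = FALSE] - Wq[-1L, , drop = FALSE]) * U)
    cnd2 <- pnorm((matrix(ti, m - 1L, m + 1L, byrow = TRUE) -
                     r * Tj) / s)
    V <- dnorm(Tj) * (cnd2[, -1L, drop = FALSE] - cnd2[, -(m + 1L), drop = FALSE])
    g_tau[j, ] <- g_tau[j, ] +
      rowSums((t(Wq)[-m, , drop = FALSE] - t(Wq)[-1L, , drop = FALSE]) * V)
  }
  list(obj = obj, g_tau = g_tau, g_rho = g_rho, n_floored = n_floored)
}

#' Control parameters for PML fitting
#'
#' @param grad_tol convergence criterion: maximum absolute (projected)
#'   gradient of the per-observation objective on the transformed scale.
#' @param iter_max,eval_max optimizer iteration/evaluation budget.
#' @param rel_tol relative tolerance passed to [nlminb()].
#' @param prob_floor floor for model cell probabilities inside logs.
#' @param threshold_cap magnitude at which thresholds of empty boundary
#'   categories are pinned.
#' @param start optional packed vector of starting values.
#' @return list of control settings for [fit_pml()].
#' @export
pml_control <- function(grad_tol = 1e-6, iter_max = 500L, eval_max = 2000L,
                        rel_tol = 1e-12, prob_floor = 1e-12,
                        threshold_cap = 6, start = NULL) {
  list(grad_tol = grad_tol, iter_max = iter_max, eval_max = eval_max,
       rel_tol = rel_tol, prob_floor = prob_floor,
       threshold_cap = threshold_cap, start = start)
}

#' Fit a factor model to ordinal data by pairwise maximum likelihood
#'
#' Maximizes the summed bivariate log-likelihood jointly over thresholds
#' and structural parameters in a single step (no separate polychoric
#' stage).  Internally the parameters are transformed to an
#' unconstrained-ish box: each item's first threshold plus logarithms of
#' the threshold gaps (enforcing within-item ordering), and inverse
#' hyperbolic tangents of correlation-type parameters (keeping them in
#' (-1, 1)).  Optimization uses [nlminb()] with the analytic gradient;
#' convergence requires the projected gradient max-norm of the
#' per-observation objective to fall below \code{control$grad_tol}.
#' Loadings are not constrained by communality: the population model
#' itself has one communality above 1.
#'
#' Items with an empty boundary category have the affected thresholds
#' pinned at \code{+-threshold_cap} (the likelihood would drive them to
#' infinity); the fit is flagged, never an error, so Monte Carlo
#' replications remain comparable.
#'
#' @param dataset an [ordinal_data()] object.
#' @param spec the [fm_spec()] to fit.
#' @param control a [pml_control()] list.
#' @return object of class \code{pml_fit}: estimated \code{thresholds},
#'   structural estimates (\code{rho} for the baseline model;
#'   \code{loadings} and \code{phi} otherwise), the implied polychoric
#'   matrix \code{implied_rho}, the maximized \code{objective} (on the
#'   \eqn{N}-scale, constant dropped), \code{converged}, iteration
#'   counts, \code{grad_norm} and character \code{flags}.
#' @export
fit_pml <- function(dataset, spec, control = pml_control()) {
  stopifnot(inherits(dataset, "ordinal_data"), inherits(spec, "fm_spec"))
  ctx <- pml_context(spec, dataset)
  k <- spec$k; m <- spec$m; K <- ctx$K
  flags <- character(0)

  # --- threshold layout: pin thresholds of empty boundary categories ----
  cap <- control$threshold_cap
  cum <- t(apply(dataset$marginals, 1L, cumsum))   # k x m
  pin_lo <- cum[, seq_len(m - 1L), drop = FALSE] == 0           # tau -> -cap
  pin_hi <- cum[, seq_len(m - 1L), drop = FALSE] == dataset$n   # tau -> +cap
  if (any(pin_lo | pin_hi)) {
    flags <- c(flags, "empty_category")
    warning("empty boundary categor(ies): the affected thresholds are ",
            "pinned at +-", cap, " and the fit is flagged")
  }
  free_th <- !(pin_lo | pin_hi)

  # start values: inverse-normal of cumulative marginal proportions
  tau0 <- qnorm(pmin(pmax(cum[, seq_len(m - 1L), drop = FALSE] / dataset$n,
                          1e-4), 1 - 1e-4))
  tau0 <- pmin(pmax(tau0, -cap + 0.2), cap - 0.2)
  if (m > 2L)   # enforce strict increase for degenerate starts
    for (i in seq_len(k)) tau0[i, ] <- cummax_strict(tau0[i, ], 1e-3)

  structural_start <- function() {
    if (spec$q == 0L) {
      r0 <- numeric(K)
      for (p in seq_len(K)) {   # coarse per-pair profile estimate
        i <- ctx$pairs[1L, p]; j <- ctx$pairs[2L, p]
        W <- ctx$pobs[, , p]
        f <- function(r) {
          P <- pmax(pair_cell_probs(r, tau0[i, ], tau0[j, ]),
                    control$prob_floor)
          -sum(W[W > 0] * log(P[W > 0]))
        }
        r0[p] <- optimize(f, c(-0.95, 0.95), tol = 1e-3)$minimum
      }
      r0
    } else {
      list(loadings = ifelse(spec$loading_mask, 0.5, 0), phi = 0.25)
    }
  }

  # --- transform: pack/unpack between optimizer vector and (tau, rho) ---
  th_layout <- lapply(seq_len(k), function(i) which(free_th[i, ]))
  n_th_free <- sum(lengths(th_layout))
  tmap <- build_transform(spec, th_layout, n_th_free, cap, pin_lo, pin_hi, ctx)

  st <- structural_start()
  z0 <- tmap$to_z(tau0, st)
  z0 <- pmin(pmax(z0, tmap$lower + 1e-9), tmap$upper - 1e-9)

  if (!is.null(control$start)) {
    up <- unpack_params(spec, control$start)
    st_user <- if (spec$q == 0L) up$rho
               else list(loadings = up$loadings,
                         phi = up$phi[spec$phi_free & lower.tri(spec$phi_free)])
    z0 <- tmap$to_z(up$thresholds, st_user)
    z0 <- pmin(pmax(z0, tmap$lower + 1e-9), tmap$upper - 1e-9)
  }

  cache <- new.env(parent = emptyenv())
  evaluate <- function(z) {
    key <- cache$z
    if (!is.null(key) && identical(key, z)) return(cache$ev)
    nat <- tmap$from_z(z)
    ev <- pml_eval(ctx, nat$tau, nat$rho, want_grad = TRUE,
                   prob_floor = control$prob_floor)
    ev$gz <- tmap$chain(z, nat, ev)
    cache$z <- z; cache$ev <- ev
    ev
  }
  fn <- function(z) -evaluate(z)$obj
  gr <- function(z) -evaluate(z)$gz

  opt <- stats::optim(z0, fn, gr, method = "L-BFGS-B",
                      lower = tmap$lower, upper = tmap$upper,
                      control = list(factr = 10, pgtol = control$grad_tol / 10,
                                     maxit = control$iter_max))
  zhat <- opt$par
  iterations <- opt$counts[[1L]]
  gn <- projected_grad_norm(gr(zhat), zhat, tmap$lower, tmap$upper)
  if (gn > control$grad_tol) {   # polish with a different algorithm
    opt2 <- nlminb(zhat, fn, gr, lower = tmap$lower, upper = tmap$upper,
                   control = list(iter.max = control$iter_max,
                                  eval.max = control$eval_max,
                                  rel.tol = control$rel_tol))
    if (opt2$objective <= opt$value) {
      zhat <- opt2$par
      iterations <- iterations + opt2$iterations
    }
    gn <- projected_grad_norm(gr(zhat), zhat, tmap$lower, tmap$upper)
  }
  converged <- gn <= control$grad_tol
  if (!converged) flags <- c(flags, "not_converged")

  nat <- tmap$from_z(zhat)
  ev <- pml_eval(ctx, nat$tau, nat$rho, want_grad = FALSE,
                 prob_floor = control$prob_floor)
  if (ev$n_floored > 0L) flags <- c(flags, "floored_cells")

  R <- diag(k)
  R[t(ctx$pairs)] <- nat$rho
  R[t(ctx$pairs[2:1, , drop = FALSE])] <- nat$rho
  out <- list(spec = spec, n = dataset$n,
              thresholds = nat$tau,
              rho = nat$rho, implied_rho = R,
              loadings = nat$loadings, phi = nat$phi,
              objective = dataset$n * ev$obj,
              objective_per_obs = ev$obj,
              converged = converged, grad_norm = gn,
              iterations = iterations,
              flags = flags, optim_message = opt$message)
  class(out) <- "pml_fit"
  out
}

# strictly increasing version of a vector (minimum gap eps)
cummax_strict <- function(x, eps) {
  for (a in seq_along(x)[-1L]) x[a] <- max(x[a], x[a - 1L] + eps)
  x
}

# Transform machinery: optimizer vector z <-> natural parameters.
# Threshold block per item: first free threshold, then log-gaps.
# Structural block: atanh(rho) (baseline) or raw loadings + atanh(phi).
build_transform <- function(spec, th_layout, n_th_free, cap, pin_lo, pin_hi,
                            ctx) {
  k <- spec$k; m <- spec$m; K <- ctx$K
  q <- spec$q
  n_struct <- spec$n_structural
  th_off <- c(0L, cumsum(lengths(th_layout)))   # offsets into z
  lower <- numeric(n_th_free + n_struct)
  upper <- numeric(n_th_free + n_struct)
  for (i in seq_len(k)) {
    nf <- length(th_layout[[i]])
    if (nf == 0L) next
    zi <- th_off[i] + seq_len(nf)
    lower[zi] <- c(-cap, rep(log(1e-4), nf - 1L))
    upper[zi] <- c(cap, rep(log(12), nf - 1L))
  }
  sidx <- n_th_free + seq_len(n_struct)
  if (q == 0L) {
    lower[sidx] <- -atanh(0.999); upper[sidx] <- atanh(0.999)
  } else {
    nl <- sum(spec$loading_mask)
    lower[sidx[seq_len(nl)]] <- -3; upper[sidx[seq_len(nl)]] <- 3
    if (n_struct > nl) {
      lower[sidx[-seq_len(nl)]] <- -atanh(0.999)
      upper[sidx[-seq_len(nl)]] <- atanh(0.999)
    }
  }

  full_tau <- function(tau_free_by_item) {
    tau <- matrix(0, k, m - 1L)
    for (i in seq_len(k)) {
      tau[i, pin_lo[i, ]] <- -cap
      tau[i, pin_hi[i, ]] <- cap
      tau[i, th_layout[[i]]] <- tau_free_by_item[[i]]
    }
    tau
  }

  to_z <- function(tau, st) {
    z <- numeric(n_th_free + n_struct)
    for (i in seq_len(k)) {
      fidx <- th_layout[[i]]
      if (!length(fidx)) next
      v <- tau[i, fidx]
      z[th_off[i] + seq_along(fidx)] <- c(v[1L],
                                          if (length(v) > 1L) log(diff(v)))
    }
    if (q == 0L) {
      z[sidx] <- atanh(st)
    } else {
      nl <- sum(spec$loading_mask)
      z[sidx[seq_len(nl)]] <- st$loadings[spec$loading_mask]
      if (n_struct > nl) z[sidx[-seq_len(nl)]] <- atanh(st$phi)
    }
    z
  }

  from_z <- function(z) {
    tau_free <- vector("list", k)
    for (i in seq_len(k)) {
      nf <- length(th_layout[[i]])
      if (!nf) { tau_free[[i]] <- numeric(0); next }
      zi <- z[th_off[i] + seq_len(nf)]
      tau_free[[i]] <- cumsum(c(zi[1L], if (nf > 1L) exp(zi[-1L])))
    }
    tau <- full_tau(tau_free)
    if (q == 0L) {
      rho <- tanh(z[sidx])
      list(tau = tau, rho = rho, loadings = NULL, phi = NULL)
    } else {
      nl <- sum(spec$loading_mask)
      L <- matrix(0, k, q)
      L[spec$loading_mask] <- z[sidx[seq_len(nl)]]
      phi <- diag(q)
      if (n_struct > nl) {
        pv <- tanh(z[sidx[-seq_len(nl)]])
        phi[spec$phi_free & lower.tri(spec$phi_free)] <- pv
        phi[upper.tri(phi)] <- t(phi)[upper.tri(phi)]
      }
      Rm <- L %*% phi %*% t(L)
      rho <- Rm[t(ctx$pairs)]
      # keep implied correlations strictly inside (-1, 1); the clip only
      # binds far from any optimum (observed cells would have prob ~ 0)
      rho <- pmin(pmax(rho, -0.9999), 0.9999)
      list(tau = tau, rho = rho, loadings = L, phi = phi)
    }
  }

  chain <- function(z, nat, ev) {
    gz <- numeric(n_th_free + n_struct)
    for (i in seq_len(k)) {
      fidx <- th_layout[[i]]
      nf <- length(fidx)
      if (!nf) next
      gt <- ev$g_tau[i, fidx]
      zi <- z[th_off[i] + seq_len(nf)]
      gz[th_off[i] + 1L] <- sum(gt)
      if (nf > 1L)
        for (a in 2:nf)
          gz[th_off[i] + a] <- exp(zi[a]) * sum(gt[a:nf])
    }
    if (q == 0L) {
      gz[sidx] <- ev$g_rho * (1 - nat$rho^2)
    } else {
      L <- nat$loadings; phi <- nat$phi
      gL <- matrix(0, k, q)
      gphi <- 0
      for (p in seq_len(K)) {
        i <- ctx$pairs[1L, p]; j <- ctx$pairs[2L, p]
        gr <- ev$g_rho[p]
        gL[i, ] <- gL[i, ] + gr * as.vector(phi %*% L[j, ])
        gL[j, ] <- gL[j, ] + gr * as.vector(phi %*% L[i, ])
        if (q >= 2L && any(spec$phi_free))
          gphi <- gphi + gr * (L[i, 1L] * L[j, 2L] + L[i, 2L] * L[j, 1L])
      }
      nl <- sum(spec$loading_mask)
      gz[sidx[seq_len(nl)]] <- gL[spec$loading_mask]
      if (n_struct > nl) {
        pv <- phi[spec$phi_free & lower.tri(spec$phi_free)]
        gz[sidx[-seq_len(nl)]] <- gphi * (1 - pv^2)
      }
    }
    gz
  }

  list(to_z = to_z, from_z = from_z, chain = chain,
       lower = lower, upper = upper)
}

projected_grad_norm <- function(g, z, lower, upper, tol = 1e-8) {
  at_lo <- z <= lower + tol
  at_hi <- z >= upper - tol
  # minimizing -obj: at a lower bound a positive gradient is admissible
  g[at_lo] <- pmin(g[at_lo], 0)
  g[at_hi] <- pmax(g[at_hi], 0)
  max(abs(g))
}

#' @export
print.pml_fit <- function(x, ...) {
  cat(sprintf("PML fit of '%s' model (k = %d, m = %d), N = %d\n",
              x$spec$model_id, x$spec$k, x$spec$m, x$n))
  cat(sprintf("  objective (N-scale): %.4f   converged: %s   |grad|: %.2e\n",
              x$objective, x$converged, x$grad_norm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.null(x$loadings)) {
    cat("  loadings:\n")
    print(round(x$loadings, 3))
    if (x$spec$q > 1L)
      cat("  factor correlation(s):",
          round(x$phi[lower.tri(x$phi)], 3), "\n")
  }
  invisible(x)
}
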