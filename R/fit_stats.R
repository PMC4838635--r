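#' Upper-tail chi-square p-value
#'
#' Survival function of the chi-square reference distribution used by
#' all fit statistics.  Negative statistic values (possible for the
#' model-comparison statistic in finite samples) return a p-value of 1.
#'
#' @param value statistic value.
#' @param df degrees of freedom, \eqn{\ge 1}.
#' @return upper-tail probability.
#' @examples
#' chisq_pvalue(7.738, 7)   # 0.356
#' @export
chisq_pvalue <- function(value, df) {
  if (any(df < 1)) stop("df must be >= 1")
  ifelse(value < 0, 1, pchisq(value, df, lower.tail = FALSE))
}

# common container for a named fit statistic
new_fit_statistic <- function(name, value, df, alpha, flags = character(),
                              extra = list()) {
  p <- chisq_pvalue(value, df)
  if (value < 0) flags <- union(flags, "negative_value")
  out <- c(list(name = name, value = value, df = df, p_value = p,
                alpha_used = alpha, reject = p < alpha, flags = flags),
           extra)
  class(out) <- "fit_statistic"
  out
}

#' @export
print.fit_statistic <- function(x, ...) {
  cat(sprintf("%s = %.3f, df = %d, p = %.4g (alpha = %.4g): %s\n",
              x$name, x$value, x$df, x$p_value, x$alpha_used,
              if (x$reject) "reject" else "retain"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Full-pattern likelihood-ratio statistic CF
#'
#' \eqn{C_F = 2N \sum_r p_r \ln(p_r / \hat\pi_r)}, comparing observed
#' full response-pattern proportions with the pattern probabilities
#' implied by the fitted model (patterns never observed contribute 0).
#' Two chi-square references are returned: \code{cf} with
#' \eqn{df_F = m^k - n - 1} (all possible patterns) and \code{cf_star}
#' with \eqn{df_F^* = u_r - n - 1} (observed patterns only); the latter
#' is clamped at 1 with a warning when nonpositive.
#'
#' @param dataset an [ordinal_data()] object.
#' @param fitted a \code{pattern_probs} table evaluated at the PML
#'   estimates of the model under test (see [all_pattern_probs()]).
#' @param n_params number of free parameters of that model.
#' @param alpha nominal test level.
#' @param prob_floor floor applied to fitted probabilities of observed
#'   patterns (with a warning).
#' @return list with components \code{cf} and \code{cf_star}
#'   (\code{fit_statistic} objects; both carry \code{u_r}).
#' @export
compute_cf <- function(dataset, fitted, n_params, alpha = 0.05,
                       prob_floor = 1e-12) {
  stopifnot(inherits(dataset, "ordinal_data"))
  pr <- dataset$pattern_counts / dataset$n
  pihat <- observed_pattern_probs(fitted, dataset)
  if (any(pihat < prob_floor)) {
    warning(sum(pihat < prob_floor), " observed pattern(s) had fitted ",
            "probability below the floor ", prob_floor)
    pihat <- pmax(pihat, prob_floor)
  }
  value <- 2 * dataset$n * sum(pr * log(pr / pihat))
  u_r <- length(pr)
  m <- dataset$m; k <- dataset$k
  df_f <- m^k - n_params - 1
  df_star <- u_r - n_params - 1
  flags_star <- character(0)
  if (df_star < 1) {
    warning("df based on observed patterns is nonpositive (", df_star,
            "); clamped at 1")
    df_star <- 1
    flags_star <- "df_clamped"
  }
  list(cf = new_fit_statistic("CF", value, df_f, alpha,
                              extra = list(u_r = u_r)),
       cf_star = new_fit_statistic("CF_star", value, df_star, alpha,
                                   flags = flags_star,
                                   extra = list(u_r = u_r)))
}

#' Model-comparison statistic CM
#'
#' \eqn{C_M = C_{F1} - C_{F0}}: the full-pattern statistic of the model
#' of interest minus that of the baseline model (all polychoric
#' correlations and thresholds free), computed on the same dataset with
#' the same pattern enumeration.  Its degrees of freedom are the
#' parameter-count difference \eqn{df_M = k(k-1)/2 + k(m-1) - n_1}.
#' Because PML estimates do not maximize the full-pattern likelihood,
#' \eqn{C_M} can be negative in finite samples; it is then reported
#' as-is (never truncated) with a flag and p-value 1.
#'
#' @param cf_model \code{fit_statistic} (or numeric value) of the model
#'   of interest.
#' @param cf_baseline \code{fit_statistic} (or numeric) of the baseline.
#' @param spec the [fm_spec()] of the model of interest (supplies
#'   \eqn{n_1}, \eqn{k}, \eqn{m}).
#' @param alpha nominal test level.
#' @return a \code{fit_statistic} named \code{CM}.
#' @export
compute_cm <- function(cf_model, cf_baseline, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "fm_spec"))
  v1 <- if (inherits(cf_model, "fit_statistic")) cf_model$value else cf_model
  v0 <- if (inherits(cf_baseline, "fit_statistic")) cf_baseline$value
        else cf_baseline
  k <- spec$k; m <- spec$m
  df_m <- k * (k - 1) / 2 + k * (m - 1) - spec$n_params
  if (df_m < 1) stop("model of interest is not nested below the baseline")
  value <- v1 - v0
  flags <- if (value < 0) "negative_finite_sample" else character(0)
  new_fit_statistic("CM", value, df_m, alpha, flags = flags)
}

#' Pairwise likelihood-ratio statistics CP
#'
#' For every item pair, \eqn{C_{P_{ij}} = 2N \sum_{x_i} \sum_{x_j}
#' p_{x_i x_j} \ln(p_{x_i x_j} / \hat\pi_{x_i x_j})} with
#' \eqn{\hat\pi} the model-implied bivariate cell probabilities at the
#' PML estimates, each on \eqn{df_P = m^2 - 2m} degrees of freedom.
#' The overall statistic is the maximum over the \eqn{k(k-1)/2} pairs,
#' tested at the Bonferroni-adjusted level
#' \eqn{\alpha^* = 2\alpha / (k(k-1))} so the family-wise error stays at
#' \eqn{\alpha}.  With dichotomous items \eqn{df_P = 0} and the
#' underlying bivariate normality hypothesis cannot be tested: the
#' function refuses.
#'
#' @param dataset an [ordinal_data()] object.
#' @param fit a [fit_pml()] result on that dataset.
#' @param alpha nominal family-wise level.
#' @param prob_floor floor for fitted cell probabilities.
#' @return object of class \code{cp_result}: \code{pair_stats} (data
#'   frame of per-pair statistics), \code{overall} (a
#'   \code{fit_statistic} at level \code{alpha_star}), \code{max_pair},
#'   \code{alpha} and \code{alpha_star}.
#' @export
compute_cp <- function(dataset, fit, alpha = 0.05, prob_floor = 1e-12) {
  stopifnot(inherits(dataset, "ordinal_data"), inherits(fit, "pml_fit"))
  m <- dataset$m; k <- dataset$k
  if (m < 3L)
    stop("CP cannot be tested with dichotomous items: df_P = m^2 - 2m = 0, ",
         "so the underlying bivariate normal distribution is untestable")
  df_p <- m^2 - 2 * m
  K <- ncol(dataset$pairs)
  alpha_star <- 2 * alpha / (k * (k - 1))
  vals <- numeric(K)
  n_floored <- 0L
  for (p in seq_len(K)) {
    i <- dataset$pairs[1L, p]; j <- dataset$pairs[2L, p]
    pobs <- dataset$pair_tables[, , p] / dataset$n
    pihat <- pair_cell_probs(fit$implied_rho[i, j],
                             fit$thresholds[i, ], fit$thresholds[j, ])
    pos <- pobs > 0
    n_floored <- n_floored + sum(pos & pihat < prob_floor)
    pihat <- pmax(pihat, prob_floor)
    vals[p] <- 2 * dataset$n * sum(pobs[pos] * log(pobs[pos] / pihat[pos]))
  }
  if (n_floored > 0L)
    warning(n_floored, " observed cell(s) had fitted probability below ",
            "the floor ", prob_floor)
  best <- which.max(vals)   # ties: first pair in (i<j) lexicographic order
  overall <- new_fit_statistic("CP", vals[best], df_p, alpha_star,
                               extra = list(n_pairs = K, alpha_family = alpha))
  structure(list(
    pair_stats = data.frame(i = dataset$pairs[1L, ], j = dataset$pairs[2L, ],
                            value = vals, df = df_p,
                            p_value = chisq_pvalue(vals, df_p)),
    overall = overall,
    max_pair = c(i = dataset$pairs[1L, best], j = dataset$pairs[2L, best]),
    alpha = alpha, alpha_star = alpha_star), class = "cp_result")
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf("CP: max over %d pairs = %.3f at pair (%d,%d), df = %d\n",
              nrow(x$pair_stats), x$overall$value, x$max_pair[1L],
              x$max_pair[2L], x$overall$df))
  cat(sprintf("  Bonferroni alpha* = %.5f (family alpha = %.3f): %s\n",
              x$alpha_star, x$alpha,
              if (x$overall$reject) "reject" else "retain"))
  invisible(x)
}

# eigenvalue-clipped correlation repair for estimated polychoric
# matrices that fail positive definiteness (possible for the baseline
# model at small N, where the pairwise estimates are unconstrained)
repair_correlation <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > eps) return(structure(R, repaired = FALSE))
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  structure(R2, repaired = TRUE)
}

#' Pattern probabilities implied by a PML fit
#'
#' Evaluates the full response-pattern table at a fit's implied
#' polychoric matrix and estimated thresholds.  A non-positive-definite
#' estimated matrix (possible for the unconstrained baseline model in
#' small samples) is repaired by eigenvalue clipping, with a warning.
#'
#' @param fit a [fit_pml()] result.
#' @param ... passed to [all_pattern_probs()].
#' @return a \code{pattern_probs} table.
#' @export
fitted_pattern_probs <- function(fit, ...) {
  stopifnot(inherits(fit, "pml_fit"))
  R <- repair_correlation(fit$implied_rho)
  if (isTRUE(attr(R, "repaired")))
    warning("estimated polychoric matrix was not positive definite; ",
            "eigenvalues clipped before pattern integration")
  all_pattern_probs(unclass(R), fit$thresholds, fit$spec$m, ...)
}

#' All applicable fit statistics for one model on one dataset
#'
#' Fits the requested model by PML and computes every applicable fit
#' statistic: \code{CF} (both degree-of-freedom variants), \code{CM}
#' against the baseline model (for structured models), and \code{CP}
#' (for \eqn{m \ge 3}).  Full-pattern statistics are skipped, with a
#' note, when \eqn{m^k} exceeds \code{max_patterns}.
#'
#' @param dataset an [ordinal_data()] object.
#' @param model an [fm_spec()] or a model id accepted by
#'   [study_model()].
#' @param alpha nominal level (for \code{CP}: family-wise level).
#' @param statistics subset of \code{c("CF", "CM", "CP")}.
#' @param baseline_fit optional pre-computed baseline [fit_pml()] (to
#'   avoid refitting when evaluating several models on one dataset).
#' @param control a [pml_control()] list.
#' @param abseps,max_patterns integration settings for the
#'   full-pattern table.
#' @return list of class \code{pml_gof} with the fit(s) and statistics.
#' @export
pml_gof <- function(dataset, model, alpha = 0.05,
                    statistics = c("CF", "CM", "CP"),
                    baseline_fit = NULL, control = pml_control(),
                    abseps = 1e-6, max_patterns = 2e5) {
  stopifnot(inherits(dataset, "ordinal_data"))
  spec <- if (inherits(model, "fm_spec")) model
          else study_model(model, k = dataset$k, m = dataset$m)
  fit <- fit_pml(dataset, spec, control)
  out <- list(fit = fit, statistics = list())
  want_cf <- "CF" %in% statistics || ("CM" %in% statistics && spec$q > 0L)
  if (want_cf && dataset$m^dataset$k <= max_patterns) {
    fitted <- fitted_pattern_probs(fit, abseps = abseps,
                                   max_patterns = max_patterns)
    cf <- compute_cf(dataset, fitted, spec$n_params, alpha = alpha)
    if ("CF" %in% statistics) {
      out$statistics$CF <- cf$cf
      out$statistics$CF_star <- cf$cf_star
    }
    if ("CM" %in% statistics && spec$q > 0L) {
      if (is.null(baseline_fit)) {
        baseline_fit <- fit_pml(dataset,
                                study_model("baseline", dataset$k, dataset$m),
                                control)
      }
      fitted0 <- fitted_pattern_probs(baseline_fit, abseps = abseps,
                                      max_patterns = max_patterns)
      cf0 <- compute_cf(dataset, fitted0,
                        baseline_fit$spec$n_params, alpha = alpha)
      out$baseline_fit <- baseline_fit
      out$statistics$CM <- compute_cm(cf$cf, cf0$cf, spec, alpha = alpha)
    }
  } else if (want_cf) {
    out$skipped_cf <- sprintf(
      "m^k = %g exceeds max_patterns = %g; CF/CM not computed",
      dataset$m^dataset$k, max_patterns)
  }
  if ("CP" %in% statistics && dataset$m >= 3L)
    out$statistics$CP <- compute_cp(dataset, fit, alpha = alpha)
  class(out) <- "pml_gof"
  out
}

#' @export
print.pml_gof <- function(x, ...) {
  print(x$fit)
  for (s in x$statistics) {
    if (inherits(s, "cp_result")) print(s) else print(s)
  }
  if (!is.null(x$skipped_cf)) cat(" ", x$skipped_cf, "\n")
  invisible(x)
}
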