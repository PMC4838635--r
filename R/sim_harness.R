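#' Monte Carlo study design
#'
#' Describes a calibration/power study: datasets are generated from the
#' population two-factor model at each combination of sample size and
#' category count, the requested models are fitted by PML, and the
#' requested fit statistics are evaluated at level \code{alpha}.
#'
#' The \code{"desk"} profile (200 replications, full-pattern statistics
#' only where the pattern table has at most 64 cells, i.e. dichotomous
#' items) is sized for interactive use; the \code{"full"} profile (1000
#' replications, full-pattern statistics in all conditions) reproduces
#' the complete study and is intended for long unattended runs, since
#' the 729- and 4096-pattern integrations dominate its runtime.
#'
#' @param sample_sizes vector of sample sizes.
#' @param category_counts vector of response-category counts.
#' @param replications Monte Carlo replications per condition.
#' @param base_seed integer; replication \code{r} of every condition
#'   uses seed \code{base_seed + r}, so any replication can be re-run in
#'   isolation and conditions share common random numbers.
#' @param alpha nominal test level.
#' @param models models fitted to each dataset.
#' @param statistics fit statistics to evaluate (applicability rules --
#'   no \code{CP} at m = 2, no \code{CM} for the baseline -- are applied
#'   automatically).
#' @param profile \code{"desk"} or \code{"full"}; presets
#'   \code{replications} and \code{cf_pattern_limit} unless those are
#'   given explicitly.
#' @param cf_pattern_limit compute \code{CF}/\code{CM} only when
#'   \eqn{m^k} does not exceed this.
#' @param abseps per-pattern integration tolerance used inside the
#'   harness; the default 1e-5 keeps the integration error three orders
#'   of magnitude below the Monte Carlo variability of the full-pattern
#'   statistics while dominating the study's runtime budget.
#' @return object of class \code{study_design}.
#' @export
study_design <- function(sample_sizes = c(200L, 500L, 1000L),
                         category_counts = c(2L, 3L, 4L),
                         replications = NULL,
                         base_seed = 1L, alpha = 0.05,
                         models = c("baseline", "one_factor", "two_factor"),
                         statistics = c("CF", "CM", "CP"),
                         profile = c("desk", "full"),
                         cf_pattern_limit = NULL,
                         abseps = 1e-5) {
  profile <- match.arg(profile)
  if (is.null(replications))
    replications <- if (profile == "desk") 200L else 1000L
  if (is.null(cf_pattern_limit))
    cf_pattern_limit <- if (profile == "desk") 64 else 2e5
  stopifnot(replications >= 1)
  structure(list(sample_sizes = as.integer(sample_sizes),
                 category_counts = as.integer(category_counts),
                 replications = as.integer(replications),
                 base_seed = as.integer(base_seed), alpha = alpha,
                 models = match.arg(models, several.ok = TRUE),
                 statistics = match.arg(statistics, several.ok = TRUE),
                 profile = profile, cf_pattern_limit = cf_pattern_limit,
                 abseps = abseps),
            class = "study_design")
}

#' Wald confidence interval for a Monte Carlo rejection rate
#'
#' \eqn{rate \pm 1.96 \sqrt{rate(1-rate)/R}}, clipped to \eqn{[0, 1]}
#' (normal approximation, no continuity correction) -- the interval
#' printed alongside every rejection rate.
#'
#' @param rate rejection rate in \eqn{[0, 1]}.
#' @param R number of replications.
#' @return named vector \code{c(lower, upper)}.
#' @examples
#' rejection_ci(0.987, 1000)   # (0.980, 0.994)
#' @export
rejection_ci <- function(rate, R) {
  stopifnot(rate >= 0, rate <= 1, R >= 1)
  half <- 1.96 * sqrt(rate * (1 - rate) / R)
  c(lower = max(0, rate - half), upper = min(1, rate + half))
}

#' Run one Monte Carlo condition
#'
#' Generates \code{design$replications} datasets of size \code{n_obs}
#' with \code{m} categories from the population model (replication
#' \code{r} seeded with \code{base_seed + r}), fits the requested models
#' by PML, evaluates the requested fit statistics, and aggregates
#' rejection rates (with Wald intervals), statistic means and SDs, the
#' moments of the observed-pattern degrees of freedom, and -- for the
#' two-factor model -- the parameter estimates for accuracy/efficiency
#' summaries.  Replication-level estimation failures are counted and
#' excluded from the affected statistics' denominators, which the
#' result reports per statistic.
#'
#' @param design a [study_design()].
#' @param n_obs sample size of this condition.
#' @param m number of categories of this condition.
#' @param verbose print per-replication progress every 50 replications?
#' @return object of class \code{condition_result}: \code{table} (one
#'   row per model/statistic), \code{estimates} (two-factor parameter
#'   draws, when fitted), \code{n_failed}, \code{n_flagged}.
#' @export
run_condition <- function(design, n_obs, m, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  R <- design$replications
  alpha <- design$alpha
  k <- 6L
  use_cf <- any(c("CF", "CM") %in% design$statistics) &&
    m^k <= design$cf_pattern_limit
  use_cp <- "CP" %in% design$statistics && m >= 3L
  structured <- setdiff(design$models, "baseline")
  need_baseline <- "baseline" %in% design$models ||
    ("CM" %in% design$statistics && use_cf && length(structured))

  rec <- list()   # rec[[model]][[stat]] = list(value, reject, df_star)
  add <- function(model, stat, value, reject, df_star = NA_real_) {
    key <- paste(model, stat, sep = ".")
    rec[[key]] <<- list(value = c(rec[[key]]$value, value),
                        reject = c(rec[[key]]$reject, reject),
                        df_star = c(rec[[key]]$df_star, df_star))
  }
  est_loadings <- NULL; est_phi <- NULL
  n_failed <- 0L; n_flagged <- 0L

  for (r in seq_len(R)) {
    if (verbose && r %% 50L == 0L)
      message(sprintf("  N = %d, m = %d: replication %d / %d", n_obs, m, r, R))
    res <- tryCatch(suppressWarnings({
      cfg <- generation_config(n_obs, m, seed = design$base_seed + r)
      dat <- simulate_ordinal(cfg)
      fits <- list()
      if (need_baseline)
        fits$baseline <- fit_pml(dat, study_model("baseline", k, m))
      for (mod in structured)
        fits[[mod]] <- fit_pml(dat, study_model(mod, k, m))
      cf0 <- NULL
      if (use_cf && need_baseline) {
        f0 <- fitted_pattern_probs(fits$baseline, abseps = design$abseps)
        cf0 <- compute_cf(dat, f0, fits$baseline$spec$n_params, alpha = alpha)
      }
      list(dat = dat, fits = fits, cf0 = cf0)
    }), error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }

    if (any(vapply(res$fits, function(f) !f$converged, logical(1))))
      n_flagged <- n_flagged + 1L

    for (mod in design$models) {
      fit <- res$fits[[mod]]
      if (is.null(fit)) next
      cf <- NULL
      if (use_cf && (("CF" %in% design$statistics) ||
                     ("CM" %in% design$statistics && mod != "baseline"))) {
        cf <- if (mod == "baseline") res$cf0 else
          suppressWarnings(compute_cf(
            res$dat, fitted_pattern_probs(fit, abseps = design$abseps),
            fit$spec$n_params, alpha = alpha))
      }
      if (!is.null(cf) && "CF" %in% design$statistics) {
        add(mod, "CF", cf$cf$value, cf$cf$reject)
        add(mod, "CF_star", cf$cf_star$value, cf$cf_star$reject,
            df_star = cf$cf_star$df)
      }
      if (!is.null(cf) && "CM" %in% design$statistics && mod != "baseline" &&
          !is.null(res$cf0)) {
        cm <- compute_cm(cf$cf, res$cf0$cf, fit$spec, alpha = alpha)
        add(mod, "CM", cm$value, cm$reject)
      }
      if (use_cp) {
        cp <- suppressWarnings(compute_cp(res$dat, fit, alpha = alpha))
        add(mod, "CP", cp$overall$value, cp$overall$reject)
      }
      if (mod == "two_factor") {
        al <- align_two_factor(fit)
        est_loadings <- rbind(est_loadings, al$loadings)
        est_phi <- c(est_phi, al$phi)
      }
    }
  }

  rows <- lapply(names(rec), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    v <- rec[[key]]
    n_used <- length(v$value)
    rr <- mean(v$reject)
    ci <- rejection_ci(rr, n_used)
    data.frame(n_obs = n_obs, m = m, model = parts[1L], statistic = parts[2L],
               R = R, n_used = n_used,
               mean = mean(v$value), sd = stats::sd(v$value),
               rejection_rate = rr, ci_lower = ci[[1L]], ci_upper = ci[[2L]],
               df = stat_df(parts[2L], parts[1L], k, m),
               mean_df = mean(v$df_star), sd_df = stats::sd(v$df_star))
  })
  structure(list(table = do.call(rbind, rows),
                 estimates = if (!is.null(est_loadings))
                   list(loadings = est_loadings, phi = est_phi),
                 n_obs = n_obs, m = m,
                 n_failed = n_failed, n_flagged = n_flagged,
                 alpha = alpha),
            class = "condition_result")
}

# nominal df of each statistic (NA for CF_star, whose df is data-driven)
stat_df <- function(stat, model, k, m) {
  n1 <- study_model(model, k, m)$n_params
  switch(stat,
         CF = m^k - n1 - 1,
         CF_star = NA_real_,
         CM = k * (k - 1) / 2 + k * (m - 1) - n1,
         CP = m^2 - 2 * m)
}

# resolve the sign indeterminacy of a two-factor fit: flip any factor
# whose loading column sums negative, adjusting phi accordingly
align_two_factor <- function(fit) {
  L <- fit$loadings
  phi12 <- fit$phi[1L, 2L]
  s <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2L, s, `*`)
  list(loadings = L[fit$spec$loading_mask], phi = phi12 * s[1L] * s[2L])
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("Condition N = %d, m = %d (failures: %d, non-converged: %d)\n",
              x$n_obs, x$m, x$n_failed, x$n_flagged))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full Monte Carlo study
#'
#' Calls [run_condition()] for every (sample size, category count)
#' combination of the design and binds the result tables.
#'
#' @param design a [study_design()].
#' @param verbose print progress?
#' @return object of class \code{study_result} with \code{table} (all
#'   conditions) and \code{conditions} (the individual
#'   \code{condition_result}s).
#' @export
run_study <- function(design, verbose = FALSE) {
  conditions <- list()
  for (n_obs in design$sample_sizes)
    for (m in design$category_counts) {
      if (verbose) message(sprintf("condition N = %d, m = %d ...", n_obs, m))
      conditions[[sprintf("N%d_m%d", n_obs, m)]] <-
        run_condition(design, n_obs, m, verbose = verbose)
    }
  structure(list(table = do.call(rbind, c(lapply(conditions, `[[`, "table"),
                                          make.row.names = FALSE)),
                 conditions = conditions, design = design),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Accuracy and efficiency of two-factor parameter estimates
#'
#' Summarizes a collection of two-factor PML estimates against the
#' population values.  Accuracy is the absolute difference between the
#' average estimate across replications and the population value (the
#' Monte Carlo bias magnitude); efficiency is the standard deviation of
#' the estimates across replications.  Both are reported per parameter
#' with grand averages over the seven loadings.
#'
#' @param estimates either a \code{condition_result}/list with an
#'   \code{estimates} element, a list of such objects (each condition is
#'   summarized separately and the grand averages averaged over
#'   conditions), or a list with components \code{loadings} (matrix,
#'   one row per replication) and \code{phi} (vector).
#' @param loadings,phi population values.
#' @return list with per-parameter \code{loading_bias},
#'   \code{loading_sd}, \code{phi_bias}, \code{phi_sd}, and grand
#'   averages \code{avg_loading_bias}, \code{avg_loading_sd}.
#' @export
accuracy_summary <- function(estimates, loadings = population_loadings(),
                             phi = population_phi()) {
  spec <- study_model("two_factor", 6L, 2L)
  truth_l <- loadings[spec$loading_mask]
  truth_p <- phi[1L, 2L]
  if (inherits(estimates, "condition_result"))
    estimates <- estimates$estimates
  if (is.list(estimates) && is.null(estimates$loadings)) {
    # several conditions: summarize each, then average the summaries
    per <- lapply(estimates, accuracy_summary, loadings = loadings, phi = phi)
    return(list(
      per_condition = per,
      avg_loading_bias = mean(vapply(per, `[[`, 0, "avg_loading_bias")),
      avg_loading_sd = mean(vapply(per, `[[`, 0, "avg_loading_sd")),
      avg_phi_bias = mean(vapply(per, `[[`, 0, "phi_bias")),
      avg_phi_sd = mean(vapply(per, `[[`, 0, "phi_sd"))))
  }
  est_l <- estimates$loadings
  est_p <- estimates$phi
  if (is.null(est_l) || nrow(est_l) == 0L) stop("no estimates supplied")
  loading_bias <- abs(colMeans(est_l) - truth_l)
  loading_sd <- apply(est_l, 2L, stats::sd)
  list(loading_bias = loading_bias,
       loading_sd = loading_sd,
       phi_bias = abs(mean(est_p) - truth_p),
       phi_sd = stats::sd(est_p),
       avg_loading_bias = mean(loading_bias),
       avg_loading_sd = mean(loading_sd))
}
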