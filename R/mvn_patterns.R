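#' Probability of a full k-dimensional response pattern
#'
#' The probability that all \eqn{k} items jointly produce the category
#' tuple \code{pattern}: the \eqn{k}-variate standard normal measure of
#' the hyper-rectangle between consecutive thresholds, evaluated with
#' the Genz-Bretz randomized quasi-Monte Carlo algorithm of
#' \pkg{mvtnorm} (the dimension-2 and -3 cases use deterministic
#' quadrature).  A fixed internal seed makes repeated evaluations
#' reproducible without disturbing the caller's RNG stream.
#'
#' @param rho \code{k x k} positive-definite correlation matrix.
#' @param tau \code{k x (m-1)} threshold matrix (or a vector common to
#'   all items).
#' @param pattern integer vector of \eqn{k} categories in 1..m.
#' @param abseps absolute integration tolerance per pattern.
#' @return scalar probability.
#' @export
pattern_prob <- function(rho, tau, pattern, abseps = 1e-6) {
  k <- nrow(rho)
  stopifnot(ncol(rho) == k, length(pattern) == k)
  if (!is.matrix(tau)) tau <- matrix(tau, k, length(tau), byrow = TRUE)
  m <- ncol(tau) + 1L
  if (any(pattern < 1L | pattern > m)) stop("category out of range")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("correlation matrix is not positive definite")
  text <- cbind(-Inf, tau, Inf)
  lower <- text[cbind(seq_len(k), pattern)]
  upper <- text[cbind(seq_len(k), pattern + 1L)]
  with_fixed_seed(191L, {
    as.numeric(mvtnorm::pmvnorm(lower = lower, upper = upper, corr = rho,
                                algorithm = mvtnorm::GenzBretz(
                                  abseps = abseps, maxpts = 25000L * k)))
  })
}

#' All m^k response-pattern probabilities
#'
#' Enumerates every possible response pattern in odometer order (the
#' last item varying fastest, matching the pattern indexing of
#' [ordinal_data()]) and integrates each one.  The total mass should be
#' 1 up to accumulated integration error; the table is renormalized to
#' sum exactly to 1 by default because the raw deficit would otherwise
#' bias likelihood-ratio statistics built from it.  Problems with more
#' than \code{max_patterns} patterns are refused outright -- full-pattern
#' machinery is only meaningful where the table is enumerable.
#'
#' @inheritParams pattern_prob
#' @param m number of categories; \code{k} is taken from \code{rho}.
#' @param renormalize divide by the total mass? (the raw deficit is
#'   recorded either way).
#' @param max_patterns refusal ceiling for \eqn{m^k}.
#' @return object of class \code{pattern_probs}: \code{prob} (length
#'   \eqn{m^k}, odometer order), \code{patterns} (\eqn{m^k \times k}
#'   category matrix), \code{deficit} (1 - raw total mass before any
#'   renormalization), plus the inputs.
#' @export
all_pattern_probs <- function(rho, tau, m, renormalize = TRUE,
                              abseps = 1e-6, max_patterns = 2e5) {
  k <- nrow(rho)
  if (!is.matrix(tau)) tau <- matrix(tau, k, length(tau), byrow = TRUE)
  stopifnot(ncol(tau) == m - 1L)
  n_pat <- m^k
  if (n_pat > max_patterns)
    stop("m^k = ", n_pat, " exceeds the enumeration ceiling (",
         max_patterns, " patterns)")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("correlation matrix is not positive definite")
  patterns <- pattern_from_index(seq_len(n_pat), m, k)
  text <- cbind(-Inf, tau, Inf)
  prob <- numeric(n_pat)
  with_fixed_seed(191L, {
    for (r in seq_len(n_pat)) {
      pat <- patterns[r, ]
      prob[r] <- as.numeric(mvtnorm::pmvnorm(
        lower = text[cbind(seq_len(k), pat)],
        upper = text[cbind(seq_len(k), pat + 1L)],
        corr = rho,
        algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                       maxpts = 25000L * k)))
    }
  })
  deficit <- 1 - sum(prob)
  if (renormalize) prob <- prob / sum(prob)
  structure(list(prob = prob, patterns = patterns, deficit = deficit,
                 m = m, k = k, renormalized = renormalize),
            class = "pattern_probs")
}

#' @export
print.pattern_probs <- function(x, ...) {
  cat(sprintf("Pattern probabilities: %d patterns (k = %d, m = %d)\n",
              length(x$prob), x$k, x$m))
  cat(sprintf("  integration deficit before renormalization: %.2e\n",
              x$deficit))
  invisible(x)
}

#' Look up fitted probabilities of observed patterns
#'
#' @param fitted a \code{pattern_probs} table.
#' @param dataset an [ordinal_data()] object on the same (k, m).
#' @return numeric vector aligned with \code{dataset$pattern_counts}.
#' @export
observed_pattern_probs <- function(fitted, dataset) {
  stopifnot(inherits(fitted, "pattern_probs"),
            inherits(dataset, "ordinal_data"),
            fitted$m == dataset$m, fitted$k == dataset$k)
  fitted$prob[dataset$pattern_index]
}
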