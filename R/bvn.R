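#' Vectorized standard bivariate normal CDF
#'
#' Computes \eqn{\Phi_2(h, k; \rho) = P(X \le h, Y \le k)} for standard
#' bivariate normal \eqn{(X, Y)} with correlation \eqn{\rho}, elementwise
#' over the recycled arguments.  This is the probability kernel of the
#' pairwise likelihood: every bivariate cell probability is a double
#' difference of four such CDF values.
#'
#' For \eqn{|\rho| \le 0.925} the single-integral reduction
#' \deqn{\Phi_2(h,k;\rho) = \Phi(h)\Phi(k) + \frac{1}{2\pi}
#'   \int_0^{\arcsin\rho} \exp\left\{-\frac{h^2 + k^2 - 2hk\sin\theta}
#'   {2\cos^2\theta}\right\} d\theta}
#' (Drezner & Wesolowsky, 1990; Genz, 2004) is evaluated with 24-point
#' Gauss-Legendre quadrature, vectorized over all inputs; absolute error
#' is below 1e-10 on this range.  For the rare \eqn{|\rho| > 0.925} the
#' scalar deterministic Miwa algorithm of \pkg{mvtnorm} is used instead.
#' Infinite bounds are handled exactly.
#'
#' @param h,k upper integration limits (may be \code{-Inf}/\code{Inf}).
#' @param rho correlations, \eqn{|\rho| < 1} (\eqn{|\rho| = 1} is refused).
#' @return numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5)          # 1/4 + asin(0.5) / (2*pi)
#' pbvnorm(Inf, 1.2, 0.9)      # = pnorm(1.2)
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- rep_len(as.numeric(rho), n)
  if (any(abs(rho) >= 1)) stop("pbvnorm: |rho| must be < 1")

  out <- numeric(n)
  neg <- (h == -Inf) | (k == -Inf)
  hInf <- is.infinite(h) & h > 0
  kInf <- is.infinite(k) & k > 0
  out[hInf] <- pnorm(k[hInf])
  out[kInf] <- pnorm(h[kInf])
  out[hInf & kInf] <- 1
  out[neg] <- 0

  main <- !(neg | hInf | kInf)
  idx <- which(main & abs(rho) <= 0.925)
  if (length(idx)) {
    gl <- gauss_legendre_nodes()
    hh <- h[idx]; kk <- k[idx]
    asr <- asin(rho[idx])
    theta <- outer(asr / 2, gl$x + 1)          # angles in (0, asin(rho))
    sn <- sin(theta)
    expo <- -(hh^2 + kk^2 - 2 * (hh * kk) * sn) / (2 * cos(theta)^2)
    out[idx] <- pnorm(hh) * pnorm(kk) +
      as.vector(exp(expo) %*% gl$w) * asr / (4 * pi)
  }
  idx2 <- which(main & abs(rho) > 0.925)
  for (i in idx2) {
    out[i] <- mvtnorm::pmvnorm(
      upper = c(h[i], k[i]),
      corr = matrix(c(1, rho[i], rho[i], 1), 2L),
      algorithm = mvtnorm::Miwa(steps = 512L))
  }
  pmin(pmax(out, 0), 1)
}

#' Standard bivariate normal density
#'
#' Elementwise \eqn{\phi_2(h, k; \rho)}; returns 0 at infinite arguments
#' (the value needed when differentiating rectangle probabilities with
#' respect to the correlation).
#'
#' @inheritParams pbvnorm
#' @return numeric vector of densities.
#' @export
dbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- rep_len(as.numeric(rho), n)
  out <- numeric(n)
  fin <- is.finite(h) & is.finite(k)
  if (any(fin)) {
    s2 <- 1 - rho[fin]^2
    out[fin] <- exp(-(h[fin]^2 - 2 * rho[fin] * h[fin] * k[fin] + k[fin]^2) /
                      (2 * s2)) / (2 * pi * sqrt(s2))
  }
  out
}

gauss_legendre_nodes <- function() {
  gl <- .pmlfa_env$gl24
  if (is.null(gl)) {
    g <- pracma::gaussLegendre(24L, -1, 1)
    gl <- list(x = g$x, w = g$w)
    .pmlfa_env$gl24 <- gl
  }
  gl
}
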