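#' Construct a factor-model specification for ordinal items
#'
#' A specification fixes the measurement design: the number of items
#' \code{k}, the common number of response categories \code{m}, and the
#' structural parameterization of the polychoric correlation matrix of
#' the underlying continuous scores.  Two families are supported:
#' \describe{
#'   \item{baseline}{the unrestricted underlying-normality model -- all
#'     \eqn{k(k-1)/2} polychoric correlations are free parameters;}
#'   \item{structured}{a factor model with loading matrix \eqn{\Lambda}
#'     (free entries given by \code{loading_mask}) and factor correlation
#'     matrix \eqn{\Phi} with unit diagonal and free off-diagonal entries
#'     given by \code{phi_free}.}
#' }
#' In both cases every item carries \eqn{m - 1} free thresholds; the
#' underlying variables are standardized (zero mean, unit variance), the
#' identification convention also used by the data generator.
#'
#' @param k number of items.
#' @param m number of response categories per item (\eqn{\ge 2}).
#' @param model_id one of \code{"baseline"}, \code{"one_factor"},
#'   \code{"two_factor"}, \code{"custom"}.
#' @param loading_mask logical \code{k x q} matrix of free loadings
#'   (\code{NULL} for the baseline model).
#' @param phi_free logical \code{q x q} symmetric matrix marking free
#'   factor correlations; the diagonal is always fixed at unity.
#' @return an object of class \code{fm_spec}.
#' @seealso [study_model()] for the pre-defined study models.
#' @export
fm_spec <- function(k, m, model_id = "custom", loading_mask = NULL,
                    phi_free = NULL) {
  stopifnot(k >= 2, m >= 2)
  k <- as.integer(k); m <- as.integer(m)
  if (is.null(loading_mask)) {
    if (!identical(model_id, "baseline"))
      stop("loading_mask is required unless model_id = 'baseline'")
    q <- 0L
    phi_free <- NULL
  } else {
    loading_mask <- as.matrix(loading_mask)
    storage.mode(loading_mask) <- "logical"
    if (nrow(loading_mask) != k) stop("loading_mask must have k rows")
    q <- ncol(loading_mask)
    if (any(rowSums(loading_mask) < 1))
      stop("every item needs at least one free loading")
    if (is.null(phi_free)) phi_free <- matrix(FALSE, q, q)
    phi_free <- as.matrix(phi_free)
    storage.mode(phi_free) <- "logical"
    if (!identical(dim(phi_free), c(q, q)) || !isTRUE(all(phi_free == t(phi_free))))
      stop("phi_free must be a symmetric q x q logical matrix")
    diag(phi_free) <- FALSE   # Phi diagonal is fixed at unity
  }
  pairs <- combn(k, 2L)
  n_thresholds <- k * (m - 1L)
  n_structural <- if (q == 0L) ncol(pairs)
                  else sum(loading_mask) + sum(phi_free[lower.tri(phi_free)])
  structure(list(
    k = k, m = m, q = q, model_id = model_id,
    loading_mask = loading_mask, phi_free = phi_free,
    pairs = pairs,
    n_thresholds = n_thresholds,
    n_structural = n_structural,
    n_params = n_thresholds + n_structural
  ), class = "fm_spec")
}

#' @export
print.fm_spec <- function(x, ...) {
  cat(sprintf("Factor model spec '%s': k = %d items, m = %d categories\n",
              x$model_id, x$k, x$m))
  cat(sprintf("  free parameters: %d (%d thresholds + %d structural)\n",
              x$n_params, x$n_thresholds, x$n_structural))
  invisible(x)
}

#' Pre-defined study models
#'
#' The three models of the simulation study: the baseline model with all
#' polychoric correlations free, a one-factor model (factor variance
#' fixed at unity), and a two-factor model whose loading pattern matches
#' the data-generating model -- items 1-3 load on factor 1, items 3-6 on
#' factor 2 (item 3 cross-loads), and the single factor correlation is
#' free.  The two-factor pattern has 7 free loadings, so its structural
#' parameter count (excluding thresholds) is 8.
#'
#' @param model_id \code{"baseline"}, \code{"one_factor"} or
#'   \code{"two_factor"}.
#' @param k number of items; the two-factor pattern is defined for
#'   \code{k = 6} only.
#' @param m number of response categories.
#' @return an [fm_spec()] object.
#' @examples
#' study_model("one_factor", k = 6, m = 2)$n_params  # 12
#' study_model("baseline",  k = 6, m = 2)$n_params   # 21
#' @export
study_model <- function(model_id = c("baseline", "one_factor", "two_factor"),
                        k = 6L, m = 2L) {
  model_id <- match.arg(model_id)
  switch(model_id,
    baseline = fm_spec(k, m, "baseline"),
    one_factor = fm_spec(k, m, "one_factor",
                         loading_mask = matrix(TRUE, k, 1L)),
    two_factor = {
      if (k != 6L) stop("the study's two-factor pattern is defined for k = 6")
      mask <- matrix(FALSE, 6L, 2L)
      mask[1:3, 1L] <- TRUE
      mask[3:6, 2L] <- TRUE
      fm_spec(k, m, "two_factor", loading_mask = mask,
              phi_free = matrix(c(FALSE, TRUE, TRUE, FALSE), 2L))
    })
}

#' Model-implied polychoric correlation matrix
#'
#' Computes the correlation matrix of the underlying continuous scores
#' implied by a structured factor model: the off-diagonal of
#' \eqn{\Lambda \Phi \Lambda'} with the diagonal reset to unity,
#' equivalently \eqn{\Sigma = \Lambda \Phi \Lambda' + \Theta} with
#' residual variances \eqn{\Theta = I - diag(\Lambda \Phi \Lambda')}.
#' A communality at or above 1 makes the corresponding residual variance
#' nonpositive (an improper solution); the matrix is still returned,
#' with a warning, as long as all implied correlations are below 1 in
#' magnitude -- the study's own population model contains one such item.
#'
#' @param spec a structured [fm_spec()].
#' @param loadings numeric \code{k x q} loading matrix; entries outside
#'   \code{spec$loading_mask} must be zero.
#' @param phi \code{q x q} factor correlation matrix (unit diagonal).
#' @return symmetric \code{k x k} correlation matrix with unit diagonal.
#' @export
implied_correlations <- function(spec, loadings, phi) {
  stopifnot(inherits(spec, "fm_spec"))
  if (spec$q == 0L)
    stop("the baseline model parameterizes correlations directly; ",
         "implied_correlations applies to structured models only")
  loadings <- as.matrix(loadings)
  stopifnot(identical(dim(loadings), c(spec$k, spec$q)))
  if (any(loadings[!spec$loading_mask] != 0))
    stop("nonzero loading outside the model's loading pattern")
  phi <- as.matrix(phi)
  stopifnot(identical(dim(phi), c(spec$q, spec$q)))
  if (any(abs(diag(phi) - 1) > 1e-12) || any(abs(phi) > 1))
    stop("phi must be a correlation matrix (unit diagonal, entries in [-1, 1])")
  lpl <- loadings %*% phi %*% t(loadings)
  if (any(diag(lpl) >= 1))
    warning("communality >= 1 for item(s) ",
            paste(which(diag(lpl) >= 1), collapse = ", "),
            ": implied residual variance is nonpositive (improper solution)")
  sigma <- lpl
  diag(sigma) <- 1
  if (any(abs(sigma[upper.tri(sigma)]) >= 1))
    stop("invalid parameters: an implied correlation is >= 1 in magnitude")
  sigma
}

#' Names and layout of the free-parameter vector
#'
#' The packed parameter vector is ordered thresholds first (item-major:
#' all thresholds of item 1, then item 2, ...), followed by the
#' structural block -- free loadings in column-major order then free
#' factor correlations for structured models, or the polychoric
#' correlations in pair order (1,2), (1,3), ..., (k-1,k) for the
#' baseline model.
#'
#' @param spec an [fm_spec()].
#' @return character vector of parameter names, in packing order.
#' @export
param_names <- function(spec) {
  stopifnot(inherits(spec, "fm_spec"))
  th <- as.vector(t(outer(seq_len(spec$k), seq_len(spec$m - 1L),
                          function(i, j) sprintf("tau%d.%d", i, j))))
  if (spec$q == 0L) {
    st <- sprintf("rho%d.%d", spec$pairs[1L, ], spec$pairs[2L, ])
  } else {
    idx <- which(spec$loading_mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
    st <- sprintf("lambda%d.%d", idx[, 1L], idx[, 2L])
    if (any(spec$phi_free)) {
      pidx <- which(spec$phi_free & lower.tri(spec$phi_free), arr.ind = TRUE)
      st <- c(st, sprintf("phi%d.%d", pidx[, 1L], pidx[, 2L]))
    }
  }
  c(th, st)
}

#' Pack model parameters into a flat named vector
#'
#' @param spec an [fm_spec()].
#' @param thresholds \code{k x (m-1)} threshold matrix, rows strictly
#'   increasing.
#' @param loadings,phi structural parameters for structured models.
#' @param rho length-\eqn{k(k-1)/2} polychoric vector (baseline model),
#'   in pair order (1,2), (1,3), ...
#' @return named numeric vector; \code{unpack_params()} inverts it.
#' @export
pack_params <- function(spec, thresholds, loadings = NULL, phi = NULL,
                        rho = NULL) {
  stopifnot(inherits(spec, "fm_spec"))
  thresholds <- validate_thresholds(thresholds, spec$k, spec$m)
  th <- as.vector(t(thresholds))
  if (spec$q == 0L) {
    if (is.null(rho) || length(rho) != ncol(spec$pairs))
      stop("baseline model needs rho of length k(k-1)/2")
    if (any(abs(rho) >= 1)) stop("correlations must lie in (-1, 1)")
    out <- c(th, rho)
  } else {
    if (is.null(loadings)) stop("structured model needs loadings")
    loadings <- as.matrix(loadings)
    st <- loadings[spec$loading_mask]   # column-major over free entries
    if (any(spec$phi_free)) {
      if (is.null(phi)) stop("model has free factor correlations: phi needed")
      pv <- phi[spec$phi_free & lower.tri(spec$phi_free)]
      if (any(abs(pv) >= 1)) stop("correlations must lie in (-1, 1)")
      st <- c(st, pv)
    }
    out <- c(th, st)
  }
  names(out) <- param_names(spec)
  out
}

#' Unpack a flat parameter vector
#'
#' @param spec an [fm_spec()].
#' @param par numeric vector as produced by [pack_params()].
#' @return list with components \code{thresholds} (\code{k x (m-1)}),
#'   and either \code{rho}/\code{rho_matrix} (baseline) or
#'   \code{loadings}, \code{phi} and the implied \code{rho_matrix}
#'   (structured models).
#' @export
unpack_params <- function(spec, par) {
  stopifnot(inherits(spec, "fm_spec"), length(par) == spec$n_params)
  k <- spec$k; m <- spec$m; q <- spec$q
  tau <- matrix(par[seq_len(k * (m - 1L))], nrow = k, byrow = TRUE)
  st <- par[-seq_len(k * (m - 1L))]
  if (q == 0L) {
    R <- diag(k)
    R[t(spec$pairs)] <- st; R[t(spec$pairs[2:1, , drop = FALSE])] <- st
    list(thresholds = tau, rho = unname(st), rho_matrix = R)
  } else {
    nl <- sum(spec$loading_mask)
    L <- matrix(0, k, q)
    L[spec$loading_mask] <- st[seq_len(nl)]
    phi <- diag(q)
    if (any(spec$phi_free)) {
      pv <- st[-seq_len(nl)]
      phi[spec$phi_free & lower.tri(spec$phi_free)] <- pv
      phi[upper.tri(phi)] <- t(phi)[upper.tri(phi)]
    }
    R <- L %*% phi %*% t(L)
    diag(R) <- 1
    list(thresholds = tau, loadings = L, phi = phi, rho_matrix = R,
         rho = R[t(spec$pairs)])
  }
}

validate_thresholds <- function(tau, k, m) {
  tau <- as.matrix(tau)
  if (m == 2L && length(tau) == k) tau <- matrix(tau, k, 1L)
  if (nrow(tau) != k || ncol(tau) != m - 1L)
    stop("thresholds must be a k x (m-1) matrix")
  if (any(!is.finite(tau)))
    stop("thresholds must be finite (boundary thresholds are implicit)")
  if (m > 2L && any(t(apply(tau, 1L, diff)) <= 0))
    stop("thresholds must be strictly increasing within each item")
  unname(tau)
}

#' Read a model specification from a YAML or JSON file
#'
#' The file either names a pre-defined study model --
#' \preformatted{k: 6
#' m: 3
#' model_id: two_factor}
#' -- or spells out a custom structure with \code{loading_mask} (a list
#' of k rows of 0/1) and optionally \code{phi_free} (a q x q 0/1
#' matrix, diagonal ignored):
#' \preformatted{k: 4
#' m: 2
#' loading_mask: [[1, 0], [1, 0], [0, 1], [0, 1]]
#' phi_free: [[0, 1], [1, 0]]}
#' JSON files use the same keys.  Requires the \pkg{yaml} (or, for
#' .json, \pkg{jsonlite}) package.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return an [fm_spec()].
#' @export
read_model_spec <- function(path) {
  cfg <- read_config_file(path)
  stopifnot(!is.null(cfg$k), !is.null(cfg$m))
  if (!is.null(cfg$model_id) && is.null(cfg$loading_mask))
    return(study_model(cfg$model_id, k = cfg$k, m = cfg$m))
  mask <- do.call(rbind, lapply(cfg$loading_mask, as.logical))
  phi_free <- if (!is.null(cfg$phi_free))
    do.call(rbind, lapply(cfg$phi_free, as.logical))
  fm_spec(cfg$k, cfg$m, model_id = cfg$model_id %||% "custom",
          loading_mask = mask, phi_free = phi_free)
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML files requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON files requires the 'jsonlite' package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unrecognized config format: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
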