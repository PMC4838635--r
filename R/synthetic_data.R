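#' Population model of the simulation study
#'
#' The data-generating two-factor model: items 1-3 load 0.90, 0.80, 0.70
#' on factor 1; items 3-6 load 0.50, 0.60, 0.70, 0.80 on factor 2 (item
#' 3 loads on both factors); the factor correlation is 0.50.  Residual
#' variances are \eqn{I - diag(\Lambda\Phi\Lambda')}, so the underlying
#' scores have unit variance.  Note that item 3's communality is 1.09,
#' i.e. its population residual variance is negative; the implied
#' correlation matrix is nevertheless positive definite.
#'
#' @return \code{population_loadings()}: 6 x 2 loading matrix;
#'   \code{population_phi()}: 2 x 2 factor correlation matrix;
#'   \code{population_sigma()}: the implied 6 x 6 correlation matrix of
#'   the underlying scores.
#' @export
population_loadings <- function() {
  rbind(c(0.9, 0), c(0.8, 0), c(0.7, 0.5),
        c(0, 0.6), c(0, 0.7), c(0, 0.8))
}

#' @rdname population_loadings
#' @export
population_phi <- function() matrix(c(1, 0.5, 0.5, 1), 2L)

#' @rdname population_loadings
#' @export
population_sigma <- function() {
  spec <- study_model("two_factor", 6L, 2L)
  suppressWarnings(implied_correlations(spec, population_loadings(),
                                        population_phi()))
}

#' Study thresholds for m response categories
#'
#' The fixed discretization cut-points of the simulation study, common
#' to all items: 0 for dichotomous items (expected proportions
#' 0.50/0.50), -0.6 and 0.6 for three categories (0.27/0.45/0.27), and
#' -1.2, 0, 1.2 for four (0.11/0.39/0.39/0.11).
#'
#' @param m number of categories, one of 2, 3, 4.
#' @return numeric vector of \code{m - 1} cut-points.
#' @export
study_thresholds <- function(m) {
  switch(as.character(m),
         "2" = 0,
         "3" = c(-0.6, 0.6),
         "4" = c(-1.2, 0, 1.2),
         stop("study thresholds are defined for m in {2, 3, 4}"))
}

#' Configuration for the ordinal data generator
#'
#' @param n sample size (number of respondents).
#' @param m number of response categories.
#' @param seed integer RNG seed; the generator is reproducible given the
#'   seed.
#' @param loadings,phi population factor model (defaults to the study's
#'   two-factor model).
#' @param thresholds cut-points: a vector common to all items (default
#'   [study_thresholds()]) or a \code{k x (m-1)} matrix.
#' @return an object of class \code{generation_config}.
#' @export
generation_config <- function(n, m, seed,
                              loadings = population_loadings(),
                              phi = population_phi(),
                              thresholds = study_thresholds(m)) {
  stopifnot(n >= 1, m >= 2)
  k <- nrow(as.matrix(loadings))
  if (is.matrix(thresholds)) {
    tau <- validate_thresholds(thresholds, k, m)
  } else {
    if (length(thresholds) != m - 1L)
      stop("thresholds inconsistent with m")
    tau <- matrix(thresholds, k, m - 1L, byrow = TRUE)
    tau <- validate_thresholds(tau, k, m)
  }
  structure(list(n = as.integer(n), m = as.integer(m), k = k,
                 seed = as.integer(seed),
                 loadings = as.matrix(loadings), phi = as.matrix(phi),
                 thresholds = tau),
            class = "generation_config")
}

#' Generate an ordinal dataset from the population model
#'
#' Draws \code{n} latent score vectors from the multivariate normal
#' distribution with the correlation matrix implied by the configured
#' loadings and factor correlations (via Cholesky factorization), then
#' discretizes each item at its thresholds: category \eqn{x} is assigned
#' when \eqn{\tau_{x-1} < x^* \le \tau_x}, so a latent score exactly at
#' a cut-point falls in the lower category.  Samples in which some
#' category is never observed are retained as-is (redrawing would bias
#' Monte Carlo rejection rates); estimation flags them downstream.
#'
#' @param config a [generation_config()].
#' @return an [ordinal_data()] object.
#' @export
simulate_ordinal <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  spec <- fm_spec(config$k, config$m, "custom",
                  loading_mask = config$loadings != 0 | config$loadings == 0)
  sigma <- suppressWarnings(
    implied_correlations(spec, config$loadings, config$phi))
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("implied correlation matrix is not ",
                                          "positive definite"))
  set.seed(config$seed)
  z <- matrix(rnorm(config$n * config$k), config$n) %*% ch
  codes <- matrix(1L, config$n, config$k)
  for (i in seq_len(config$k))
    codes[, i] <- 1L + rowSums(outer(z[, i], config$thresholds[i, ], ">"))
  ordinal_data(codes, m = config$m)
}

#' Ordinal response dataset
#'
#' Wraps an \code{n x k} matrix of integer response codes in 1..m and
#' precomputes the two summaries all estimation and fit machinery works
#' from: the \eqn{m \times m} contingency table of every item pair, and
#' the counts of full response patterns.
#'
#' @param codes integer matrix, one row per respondent, codes in 1..m.
#' @param m number of categories; defaults to \code{max(codes)}.
#' @return object of class \code{ordinal_data} with elements
#'   \code{codes}, \code{n}, \code{k}, \code{m}, \code{pairs} (2 x K
#'   index matrix), \code{pair_tables} (\code{m x m x K} count array),
#'   \code{patterns} (\code{u_r x k} matrix of distinct observed
#'   patterns), \code{pattern_counts} (length \code{u_r}) and
#'   \code{marginals} (\code{k x m} category counts).
#' @export
ordinal_data <- function(codes, m = max(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (any(is.na(codes)) || any(codes < 1L) || any(codes > m))
    stop("codes must be integers in 1..m with no missing values")
  n <- nrow(codes); k <- ncol(codes); m <- as.integer(m)
  pairs <- combn(k, 2L)
  K <- ncol(pairs)
  pair_tables <- array(0L, c(m, m, K))
  for (p in seq_len(K)) {
    tab <- tabulate((codes[, pairs[1L, p]] - 1L) * m + codes[, pairs[2L, p]],
                    nbins = m * m)
    pair_tables[, , p] <- matrix(tab, m, m, byrow = TRUE)
  }
  # base-m pattern encoding, item k varying fastest (odometer order)
  id <- as.vector((codes - 1L) %*% m^((k - 1L):0)) + 1
  tab <- table(id)
  uid <- as.numeric(names(tab))
  patterns <- pattern_from_index(uid, m, k)
  marginals <- t(apply(codes, 2L, tabulate, nbins = m))
  structure(list(codes = codes, n = n, k = k, m = m, pairs = pairs,
                 pair_tables = pair_tables, patterns = patterns,
                 pattern_counts = as.integer(tab),
                 pattern_index = uid,
                 marginals = marginals),
            class = "ordinal_data")
}

# decode 1-based odometer pattern indices into category codes
pattern_from_index <- function(idx, m, k) {
  idx0 <- idx - 1
  out <- matrix(0L, length(idx), k)
  for (j in k:1) {
    out[, j] <- as.integer(idx0 %% m) + 1L
    idx0 <- idx0 %/% m
  }
  out
}

#' @export
print.ordinal_data <- function(x, ...) {
  cat(sprintf("Ordinal dataset: n = %d respondents, k = %d items, m = %d categories\n",
              x$n, x$k, x$m))
  cat(sprintf("  distinct observed response patterns u_r = %d (of %g possible)\n",
              length(x$pattern_counts), x$m^x$k))
  invisible(x)
}

#' Recode responses to consecutive category ranks
#'
#' Maps the observed distinct values of each column (or of the whole
#' matrix when \code{per_item = FALSE}) to consecutive integers 1, 2,
#' ... by rank.  Because PML estimation depends on the data only through
#' ordinal comparisons, fitting is invariant under any strictly
#' increasing relabeling of the codes once they are canonicalized.
#'
#' @param codes integer matrix of (possibly non-consecutive) codes.
#' @param per_item recode each item separately?
#' @return integer matrix of ranks.
#' @export
canonicalize_codes <- function(codes, per_item = FALSE) {
  codes <- as.matrix(codes)
  if (per_item) {
    apply(codes, 2L, function(x) match(x, sort(unique(x))))
  } else {
    lev <- sort(unique(as.vector(codes)))
    matrix(match(codes, lev), nrow(codes), ncol(codes))
  }
}

#' Read and write ordinal datasets as CSV
#'
#' Datasets are stored as headered CSV of 1-based integer category
#' codes, one column per item.
#'
#' @param x an [ordinal_data()] object.
#' @param path file path.
#' @param m number of categories (defaults to the maximum code found).
#' @return \code{read_ordinal_csv()} returns an [ordinal_data()] object;
#'   \code{write_ordinal_csv()} returns \code{path} invisibly.
#' @export
write_ordinal_csv <- function(x, path) {
  stopifnot(inherits(x, "ordinal_data"))
  df <- as.data.frame(x$codes)
  names(df) <- sprintf("item%d", seq_len(x$k))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ordinal_csv
#' @export
read_ordinal_csv <- function(path, m = NULL) {
  df <- read.csv(path)
  codes <- as.matrix(df)
  if (is.null(m)) m <- max(codes)
  ordinal_data(codes, m = m)
}

#' Read a data-generation configuration from YAML or JSON
#'
#' Recognized keys: \code{n}, \code{m}, \code{seed} (required), and
#' optional \code{loadings} (list of rows), \code{phi}, and
#' \code{thresholds} (vector, or list of per-item rows); unspecified
#' structure defaults to the study's population model.
#'
#' @param path file path (.yaml/.yml/.json).
#' @return a [generation_config()].
#' @export
read_generation_config <- function(path) {
  cfg <- read_config_file(path)
  stopifnot(!is.null(cfg$n), !is.null(cfg$m), !is.null(cfg$seed))
  args <- list(n = cfg$n, m = cfg$m, seed = cfg$seed)
  if (!is.null(cfg$loadings))
    args$loadings <- do.call(rbind, lapply(cfg$loadings, as.numeric))
  if (!is.null(cfg$phi)) args$phi <- do.call(rbind, lapply(cfg$phi, as.numeric))
  if (!is.null(cfg$thresholds)) {
    th <- cfg$thresholds
    args$thresholds <- if (is.list(th)) do.call(rbind, lapply(th, as.numeric))
                       else as.numeric(th)
  }
  do.call(generation_config, args)
}
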