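#' Specification for a synthetic labeled feature table
#'
#' Describes the generator that stands in for image-derived feature vectors:
#' continuous features, a small informative subset whose class-conditional
#' means differ, the remaining dimensions pure nuisance, and an optional
#' class imbalance.
#'
#' @param n_samples number of samples (>= 10).
#' @param n_features total number of feature columns.
#' @param n_informative number of label-informative columns
#'   (<= `n_features`); these are the first `n_informative` columns.
#' @param effect_size class-conditional mean shift on each informative
#'   column, in SD units (features have unit variance within class).
#' @param minority_fraction fraction of samples in the minority class
#'   (class 1), in (0, 0.5]. Counts are rounded; each class must keep at
#'   least 2 samples.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_features()]
#' @export
synthetic_spec <- function(n_samples, n_features, n_informative,
                           effect_size = 1, minority_fraction = 0.5,
                           seed = 1L) {
  s <- structure(list(n_samples = as.integer(n_samples),
                      n_features = as.integer(n_features),
                      n_informative = as.integer(n_informative),
                      effect_size = as.numeric(effect_size),
                      minority_fraction = as.numeric(minority_fraction),
                      seed = as.integer(seed)),
                 class = "synthetic_spec")
  if (s$n_informative > s$n_features) {
    stop("synthetic_spec: n_informative (", s$n_informative,
         ") exceeds n_features (", s$n_features, ")")
  }
  if (s$n_samples < 10L) stop("synthetic_spec: n_samples must be >= 10")
  if (s$minority_fraction <= 0 || s$minority_fraction > 0.5) {
    stop("synthetic_spec: minority_fraction must lie in (0, 0.5]")
  }
  n1 <- round(s$minority_fraction * s$n_samples)
  if (n1 < 2 || s$n_samples - n1 < 2) {
    stop("synthetic_spec: minority_fraction * n_samples must leave >= 2 ",
         "samples per class")
  }
  s
}

#' Generate a synthetic labeled feature table
#'
#' Informative columns are drawn from class-conditional unit-variance
#' Gaussians: mean 0 for class 0 and mean `effect_size` for class 1.
#' The remaining columns are standard Gaussian noise independent of the
#' label. Class 1 is the minority class with
#' `round(minority_fraction * n_samples)` rows.
#'
#' @param spec a [synthetic_spec()].
#' @return A [feature_table()] with an `informative` attribute giving the
#'   indices of the signal-carrying columns.
#' @examples
#' ft <- generate_features(synthetic_spec(100, 20, 5, effect_size = 2,
#'                                        seed = 42))
#' attr(ft, "informative")
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n1 <- as.integer(round(spec$minority_fraction * spec$n_samples))
  n0 <- spec$n_samples - n1
  labels <- c(rep(0L, n0), rep(1L, n1))
  x <- local_seed(spec$seed, {
    m <- matrix(rnorm(spec$n_samples * spec$n_features),
                spec$n_samples, spec$n_features)
    if (spec$n_informative > 0L && spec$effect_size != 0) {
      shift <- matrix(0, spec$n_samples, spec$n_informative)
      shift[labels == 1L, ] <- spec$effect_size
      m[, seq_len(spec$n_informative)] <-
        m[, seq_len(spec$n_informative), drop = FALSE] + shift
    }
    m
  })
  ft <- feature_table(x, labels)
  attr(ft, "informative") <- seq_len(spec$n_informative)
  ft
}

#' Specification for a multi-run (mean, SD) result table
#'
#' Describes per-algorithm stochastic results: each alternative x criterion
#' cell is a Gaussian N(mu_ij, sigma_ij) from which `n_runs` independent run
#' values are drawn; the table records their sample mean and SD. This is the
#' input the TOPSIS ranking stack consumes.
#'
#' @param mean_matrix numeric L x K matrix of cell means.
#' @param sd_matrix positive numeric L x K matrix of cell SDs.
#' @param n_runs number of simulated runs per cell (>= 2).
#' @param seed integer root seed. One sub-seed per alternative (row) is
#'   derived as `seed + row - 1`, so rows with equal parameters and equal
#'   sub-seeds reproduce identically.
#' @return An object of class `result_table_spec`.
#' @export
result_table_spec <- function(mean_matrix, sd_matrix, n_runs, seed = 1L) {
  mean_matrix <- as.matrix(mean_matrix)
  sd_matrix <- as.matrix(sd_matrix)
  if (!all(dim(mean_matrix) == dim(sd_matrix))) {
    stop("result_table_spec: mean and sd matrices must have equal shape")
  }
  if (any(sd_matrix <= 0)) {
    stop("result_table_spec: all sd_matrix entries must be > 0")
  }
  if (n_runs < 2) stop("result_table_spec: n_runs must be >= 2")
  structure(list(mean_matrix = mean_matrix, sd_matrix = sd_matrix,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "result_table_spec")
}

#' Simulate a multi-run result table
#'
#' @param spec a [result_table_spec()].
#' @param row_seeds optional integer vector of per-alternative sub-seeds
#'   (default `seed + 0:(L-1)`).
#' @return list with `mean` and `sd` L x K matrices of sample statistics
#'   (SD with the n-1 denominator) and `n_runs`.
#' @export
generate_result_table <- function(spec, row_seeds = NULL) {
  stopifnot(inherits(spec, "result_table_spec"))
  L <- nrow(spec$mean_matrix); K <- ncol(spec$mean_matrix)
  if (is.null(row_seeds)) row_seeds <- spec$seed + seq_len(L) - 1L
  stopifnot(length(row_seeds) == L)
  m <- matrix(0, L, K, dimnames = dimnames(spec$mean_matrix))
  s <- m
  for (i in seq_len(L)) {
    draws <- local_seed(row_seeds[i], {
      matrix(rnorm(spec$n_runs * K,
                   mean = rep(spec$mean_matrix[i, ], each = spec$n_runs),
                   sd = rep(spec$sd_matrix[i, ], each = spec$n_runs)),
             spec$n_runs, K)
    })
    m[i, ] <- colMeans(draws)
    s[i, ] <- apply(draws, 2, sd)
  }
  list(mean = m, sd = s, n_runs = spec$n_runs)
}
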