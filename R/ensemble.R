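#' Half-quadratic aggregation configuration
#'
#' @param loss HQ loss family; only `"welsch"` is implemented (auxiliary
#'   weights `alpha_n = exp(-r_n^2 / (2 sigma_h^2))`).
#' @param kernel_sigma_mode `"adaptive"` (sigma_h = mean residual + 1e-8,
#'   refreshed each iteration) or `"fixed"`.
#' @param kernel_sigma kernel width used when `kernel_sigma_mode = "fixed"`.
#' @param consensus_sigma Gaussian SD of the consensus/trust kernel
#'   (default 1, on the rank scale).
#' @param max_iterations iteration cap for the alternating updates.
#' @param tolerance stop when the largest componentwise change of the
#'   aggregate falls below this.
#' @return an object of class `aggregation_config`.
#' @export
aggregation_config <- function(loss = "welsch",
                               kernel_sigma_mode = c("adaptive", "fixed"),
                               kernel_sigma = 1,
                               consensus_sigma = 1,
                               max_iterations = 200L,
                               tolerance = 1e-9) {
  loss <- match.arg(loss, "welsch")
  kernel_sigma_mode <- match.arg(kernel_sigma_mode)
  cfg <- structure(list(loss = loss, kernel_sigma_mode = kernel_sigma_mode,
                        kernel_sigma = as.numeric(kernel_sigma),
                        consensus_sigma = as.numeric(consensus_sigma),
                        max_iterations = as.integer(max_iterations),
                        tolerance = as.numeric(tolerance)),
                   class = "aggregation_config")
  if (cfg$kernel_sigma <= 0 || cfg$consensus_sigma <= 0) {
    stop("aggregation_config: sigmas must be > 0")
  }
  if (cfg$tolerance <= 0) stop("aggregation_config: tolerance must be > 0")
  cfg
}

as_rank_matrix <- function(rankings) {
  if (is.matrix(rankings)) rankings <- lapply(seq_len(nrow(rankings)),
                                              function(i) rankings[i, ])
  if (!is.list(rankings) || length(rankings) < 2L) {
    stop("hq_aggregate: need >= 2 rankings")
  }
  len <- lengths(rankings)
  if (length(unique(len)) != 1L) {
    stop("hq_aggregate: rankings differ in length (",
         paste(unique(len), collapse = ", "), ")")
  }
  do.call(rbind, lapply(rankings, as.numeric))
}

#' Robust half-quadratic aggregation of rank vectors
#'
#' Minimizes `(1/2) sum_n h(||S^n - S*||_2)` over the aggregate `S*` for a
#' half-quadratic (Welsch) loss `h`, by the multiplicative-form
#' alternation: auxiliary weights
#' `alpha_n = exp(-||S^n - S*||^2 / (2 sigma_h^2))` followed by the
#' weighted mean `S* = sum alpha_n S^n / sum alpha_n`, initialized at the
#' elementwise mean. Outlying rankings receive exponentially small weight.
#' For N = 2 the aggregate is the exact elementwise midpoint (symmetry).
#'
#' @param rankings list of N >= 2 numeric rank vectors of equal length K
#'   (or an N x K matrix, one ranking per row).
#' @param cfg an [aggregation_config()].
#' @return object of class `aggregation_result`: `s_star` (length K,
#'   lower = better), `alphas`, `weights` (`alpha / sum(alpha)`),
#'   `n_iterations`, `objective` (per-iteration surrogate objective,
#'   non-increasing in fixed-sigma mode), `final_ranks`.
#' @examples
#' hq_aggregate(list(c(6, 5, 7, 8, 1, 2, 3, 4),
#'                   c(7, 5, 6, 8, 1, 2, 3, 4)))$s_star
#' @export
hq_aggregate <- function(rankings, cfg = aggregation_config()) {
  stopifnot(inherits(cfg, "aggregation_config"))
  s <- as_rank_matrix(rankings)
  n <- nrow(s)
  s_star <- colMeans(s)
  alphas <- rep(1 / n, n)
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    resid <- sqrt(rowSums(sweep(s, 2, s_star)^2))
    sigma_h <- if (cfg$kernel_sigma_mode == "adaptive") {
      mean(resid) + 1e-8
    } else {
      cfg$kernel_sigma
    }
    alphas <- exp(-resid^2 / (2 * sigma_h^2))
    if (sum(alphas) < .Machine$double.xmin) alphas <- rep(1 / n, n)
    # Welsch surrogate value at the current iterate (fixed-sigma descent)
    objective <- c(objective,
                   0.5 * sum(sigma_h^2 * (1 - exp(-resid^2 / (2 * sigma_h^2)))))
    s_new <- colSums(s * alphas) / sum(alphas)
    delta <- max(abs(s_new - s_star))
    s_star <- s_new
    if (delta < cfg$tolerance || iter >= cfg$max_iterations) break
  }
  weights <- alphas / sum(alphas)
  structure(list(s_star = as.numeric(s_star), alphas = as.numeric(alphas),
                 weights = as.numeric(weights), n_iterations = iter,
                 objective = objective,
                 final_ranks = final_ranks(s_star)),
            class = "aggregation_result")
}

#' Consensus index of an aggregated ranking
#'
#' Gaussian-kernel agreement between the aggregate and each input ranking:
#' `q_kn = exp(-(S*_k - S^n_k)^2 / (2 sigma^2))` (the pdf ratio
#' `N_sigma(S*_k - S^n_k) / N_sigma(0)`), averaged over all K x N cells.
#' Equals 1 iff every ranking coincides with the aggregate.
#'
#' @param rankings list/matrix of rank vectors (as in [hq_aggregate()]).
#' @param s_star aggregated score vector.
#' @param cfg an [aggregation_config()] (uses `consensus_sigma`).
#' @return scalar in `(0, 1]`.
#' @export
consensus_index <- function(rankings, s_star, cfg = aggregation_config()) {
  s <- as_rank_matrix(rankings)
  if (ncol(s) != length(s_star)) {
    stop("consensus_index: s_star length mismatch")
  }
  q <- exp(-sweep(s, 2, s_star)^2 / (2 * cfg$consensus_sigma^2))
  mean(q)
}

#' Trust level of an aggregated ranking
#'
#' HQ-weighted variant of the consensus index:
#' `T = (1/K) sum_k sum_n w_n q_kn` with the half-quadratic weights
#' `w_n = alpha_n / sum(alpha_j)`. Identical to the consensus index when
#' the weights are uniform.
#'
#' @inheritParams consensus_index
#' @param weights per-ranking weights summing to 1.
#' @return scalar in `(0, 1]`.
#' @export
trust_level <- function(rankings, s_star, weights,
                        cfg = aggregation_config()) {
  s <- as_rank_matrix(rankings)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("trust_level: weights must sum to 1")
  }
  q <- exp(-sweep(s, 2, s_star)^2 / (2 * cfg$consensus_sigma^2))
  sum(weights * rowSums(q)) / ncol(s)
}

#' Ordinal ranks from aggregated scores
#'
#' Ranks ascending aggregated scores (lower score = better alternative);
#' ties are broken by ascending alternative index.
#'
#' @param s_star numeric vector of finite aggregated scores.
#' @return integer permutation of `1..length(s_star)`.
#' @examples
#' final_ranks(c(6.5, 5, 6.5, 8, 1, 2, 3, 4))
#' @export
final_ranks <- function(s_star) {
  if (any(!is.finite(s_star))) stop("final_ranks: non-finite scores")
  ord <- order(s_star, seq_along(s_star))
  rk <- integer(length(s_star)); rk[ord] <- seq_along(s_star)
  rk
}

#' Benchmark selector variants with the full ranking stack
#'
#' Builds the (mean, SD) decision matrix from per-variant multi-run
#' statistics, computes the A-TOPSIS and H-TOPSIS rank vectors, fuses them
#' by half-quadratic aggregation, and emits the ranking table with
#' consensus and trust footers. The default criteria are the four
#' optimization goals: accuracy, F2 and AUC as benefits and the selected
#' feature count as a cost.
#'
#' @param per_variant_stats list of `run_statistics` (see
#'   [multi_run_stats()]), one per selector variant; or `NULL` when
#'   `rank_matrix` is given.
#' @param criteria metric names to use as criteria.
#' @param directions `"benefit"`/`"cost"` per criterion.
#' @param w_mean,w_sd A-TOPSIS combination weights.
#' @param cfg an [aggregation_config()].
#' @param rank_matrix optional N x L matrix of precomputed rank vectors
#'   (one method per row); bypasses the TOPSIS stage and aggregates these
#'   directly.
#' @param labels alternative labels (default variant names).
#' @return object of class `benchmark_ranking`: `table` (data.frame with
#'   variant, per-criterion mean/sd, h_rank, a_rank, r_star, final_rank),
#'   `consensus`, `trust`, `aggregation` (the [hq_aggregate()] result).
#' @export
run_benchmark <- function(per_variant_stats = NULL,
                          criteria = c("accuracy", "f2", "auc",
                                       "n_selected"),
                          directions = c("benefit", "benefit", "benefit",
                                         "cost"),
                          w_mean = 0.5, w_sd = 0.5,
                          cfg = aggregation_config(),
                          rank_matrix = NULL, labels = NULL) {
  if (is.null(rank_matrix)) {
    if (length(per_variant_stats) < 2L) {
      stop("run_benchmark: need >= 2 variants")
    }
    pull <- function(rs, met, col) {
      rs$stats[[col]][match(met, rs$stats$metric)]
    }
    mean_m <- t(vapply(per_variant_stats,
                       function(rs) vapply(criteria, pull, numeric(1),
                                           rs = rs, col = "mean"),
                       numeric(length(criteria))))
    sd_m <- t(vapply(per_variant_stats,
                     function(rs) vapply(criteria, pull, numeric(1),
                                         rs = rs, col = "sd"),
                     numeric(length(criteria))))
    # H-TOPSIS needs strictly positive sigmas; a deterministic metric
    # (sd 0 across runs) gets a negligible floor
    sd_m <- pmax(sd_m, 1e-9)
    if (is.null(labels)) {
      labels <- vapply(per_variant_stats, function(rs) rs$transfer,
                       character(1))
    }
    dm <- decision_matrix(mean_m, sd_m, directions, labels, criteria)
    h_rank <- h_topsis_rank(dm)
    a_rank <- a_topsis_rank(dm, w_mean, w_sd)
    rank_matrix <- rbind(h_topsis = as.integer(h_rank),
                         a_topsis = as.integer(a_rank))
  } else {
    rank_matrix <- as.matrix(rank_matrix)
    h_rank <- rank_matrix[1L, ]
    a_rank <- rank_matrix[2L, ]
    if (is.null(labels)) labels <- paste0("A", seq_len(ncol(rank_matrix)))
    mean_m <- sd_m <- NULL
  }
  agg <- hq_aggregate(rank_matrix, cfg)
  cons <- consensus_index(rank_matrix, agg$s_star, cfg)
  trust <- trust_level(rank_matrix, agg$s_star, agg$weights, cfg)
  tab <- data.frame(variant = labels,
                    h_rank = as.integer(h_rank),
                    a_rank = as.integer(a_rank),
                    r_star = agg$s_star,
                    final_rank = agg$final_ranks)
  if (!is.null(mean_m)) {
    for (j in seq_along(criteria)) {
      tab[[paste0(criteria[j], "_mean")]] <- mean_m[, j]
      tab[[paste0(criteria[j], "_sd")]] <- sd_m[, j]
    }
  }
  structure(list(table = tab, consensus = cons, trust = trust,
                 aggregation = agg),
            class = "benchmark_ranking")
}

#' @export
print.benchmark_ranking <- function(x, ...) {
  print(x$table, digits = 5)
  cat(sprintf("consensus index: %.4f\ntrust level:     %.4f\n",
              x$consensus, x$trust))
  invisible(x)
}

#' Write a benchmark ranking table as CSV with consensus/trust footers
#'
#' @param x a `benchmark_ranking` (see [run_benchmark()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(x, path) {
  stopifnot(inherits(x, "benchmark_ranking"))
  write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  cat(sprintf("consensus,%.6f\ntrust,%.6f\n", x$consensus, x$trust),
      file = path, append = TRUE)
  invisible(path)
}
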