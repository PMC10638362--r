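#' Hellinger distance between two univariate Gaussians
#'
#' Closed form:
#' `D = sqrt(1 - sqrt(2*s1*s2/(s1^2+s2^2)) * exp(-(mu1-mu2)^2 / (4*(s1^2+s2^2))))`.
#' Symmetric, in `[0, 1]`, zero iff the distributions coincide.
#'
#' The `strict_printed` variant replaces `(mu1-mu2)^2` by `mu1^2 + mu2^2`;
#' it is provided for comparison only since it is not a distance (it
#' violates `D(h, h) = 0`).
#'
#' @param mu1,sigma1 mean and SD of the first Gaussian (`sigma1 > 0`).
#' @param mu2,sigma2 mean and SD of the second Gaussian (`sigma2 > 0`).
#' @param strict_printed logical, default FALSE.
#' @return scalar distance.
#' @examples
#' hellinger_distance(0, 1, 1, 1)  # sqrt(1 - exp(-1/8))
#' @export
hellinger_distance <- function(mu1, sigma1, mu2, sigma2,
                               strict_printed = FALSE) {
  if (sigma1 <= 0 || sigma2 <= 0) {
    stop("hellinger_distance: sigmas must be > 0")
  }
  s2sum <- sigma1^2 + sigma2^2
  num <- if (strict_printed) mu1^2 + mu2^2 else (mu1 - mu2)^2
  inner <- sqrt(2 * sigma1 * sigma2 / s2sum) * exp(-0.25 * num / s2sum)
  sqrt(max(0, 1 - inner))
}

#' Decision matrix of stochastic algorithm results
#'
#' L alternatives by K criteria, with a mean layer and an SD layer (one
#' Gaussian `N(mu_ij, sigma_ij)` per cell) and a direction per criterion.
#'
#' @param mean_matrix numeric L x K matrix of per-criterion means.
#' @param sd_matrix numeric L x K matrix of per-criterion SDs (>= 0;
#'   strictly positive wherever H-TOPSIS is applied).
#' @param directions character vector of length K, each `"benefit"`
#'   (larger is better) or `"cost"`.
#' @param alternatives optional row labels.
#' @param criteria optional column labels.
#' @return an object of class `decision_matrix`.
#' @export
decision_matrix <- function(mean_matrix, sd_matrix, directions,
                            alternatives = NULL, criteria = NULL) {
  mean_matrix <- as.matrix(mean_matrix); sd_matrix <- as.matrix(sd_matrix)
  if (!all(dim(mean_matrix) == dim(sd_matrix))) {
    stop("decision_matrix: mean and sd shapes disagree")
  }
  if (length(directions) == 1L) {
    directions <- rep(directions, ncol(mean_matrix))
  }
  if (length(directions) != ncol(mean_matrix)) {
    stop("decision_matrix: need one direction per criterion")
  }
  if (!all(directions %in% c("benefit", "cost"))) {
    stop("decision_matrix: directions must be 'benefit' or 'cost'")
  }
  if (any(sd_matrix < 0)) stop("decision_matrix: sd entries must be >= 0")
  if (is.null(alternatives)) {
    alternatives <- paste0("A", seq_len(nrow(mean_matrix)))
  }
  if (is.null(criteria)) criteria <- paste0("C", seq_len(ncol(mean_matrix)))
  dimnames(mean_matrix) <- dimnames(sd_matrix) <- list(alternatives, criteria)
  structure(list(mean_matrix = mean_matrix, sd_matrix = sd_matrix,
                 directions = directions, alternatives = alternatives,
                 criteria = criteria),
            class = "decision_matrix")
}

# descending-closeness ranks with ascending-index tie-break
rank_desc <- function(xi) {
  ord <- order(-xi, seq_along(xi))
  rk <- integer(length(xi)); rk[ord] <- seq_along(xi)
  rk
}

#' TOPSIS relative-closeness coefficients
#'
#' Columns are vector-normalized (divided by their Euclidean norm) and
#' weighted; the positive/negative ideal solutions are the per-criterion
#' best/worst values under the criterion direction; separations are
#' weighted Euclidean distances and closeness is `d- / (d+ + d-)`.
#' When an alternative is simultaneously at zero distance from both ideals
#' (all alternatives identical), its closeness is defined as 0.5.
#'
#' @param matrix numeric L x K matrix (L >= 2).
#' @param directions `"benefit"`/`"cost"` per column (recycled if scalar).
#' @param weights criterion weights summing to 1 (default equal).
#' @return numeric closeness vector in `[0, 1]`, one entry per alternative.
#' @export
topsis_closeness <- function(matrix, directions = "benefit",
                             weights = NULL) {
  matrix <- as.matrix(matrix)
  L <- nrow(matrix); K <- ncol(matrix)
  if (L < 2L) stop("topsis_closeness: need >= 2 alternatives")
  if (length(directions) == 1L) directions <- rep(directions, K)
  if (!all(directions %in% c("benefit", "cost"))) {
    stop("topsis_closeness: directions must be 'benefit' or 'cost'")
  }
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("topsis_closeness: weights must sum to 1")
  }
  norms <- sqrt(colSums(matrix^2))
  zero <- norms < .Machine$double.eps
  if (any(zero)) {
    stop("topsis_closeness: zero-norm criterion column: ",
         paste(which(zero), collapse = ", "))
  }
  v <- sweep(sweep(matrix, 2, norms, "/"), 2, weights, "*")
  pis <- nis <- numeric(K)
  for (j in seq_len(K)) {
    if (directions[j] == "benefit") {
      pis[j] <- max(v[, j]); nis[j] <- min(v[, j])
    } else {
      pis[j] <- min(v[, j]); nis[j] <- max(v[, j])
    }
  }
  dpos <- sqrt(rowSums(sweep(v, 2, pis)^2))
  dneg <- sqrt(rowSums(sweep(v, 2, nis)^2))
  tot <- dpos + dneg
  xi <- ifelse(tot < .Machine$double.eps, 0.5, dneg / tot)
  as.numeric(xi)
}

#' A-TOPSIS ranking of stochastic algorithms
#'
#' Two-layer TOPSIS: a closeness vector is computed from the mean matrix
#' (criterion directions as given) and one from the SD matrix (smaller SD
#' always better); the two vectors are stacked into an L x 2 benefit
#' matrix that a second TOPSIS pass combines with weights
#' `(w_mean, w_sd)`. Alternatives are ranked by descending global
#' closeness, ties broken by ascending index.
#'
#' @param dm a [decision_matrix()].
#' @param w_mean,w_sd combination weights (non-negative, sum 1; default
#'   0.5 each).
#' @return integer rank vector (a permutation of `1..L`; 1 = best), with
#'   attribute `closeness`.
#' @export
a_topsis_rank <- function(dm, w_mean = 0.5, w_sd = 0.5) {
  stopifnot(inherits(dm, "decision_matrix"))
  if (w_mean < 0 || w_sd < 0 || abs(w_mean + w_sd - 1) > 1e-9) {
    stop("a_topsis_rank: w_mean + w_sd must equal 1, both >= 0")
  }
  xi_mean <- topsis_closeness(dm$mean_matrix, dm$directions)
  xi_sd <- topsis_closeness(dm$sd_matrix, "cost")
  combined <- cbind(mean = xi_mean, sd = xi_sd)
  if (any(sqrt(colSums(combined^2)) < .Machine$double.eps)) {
    # a degenerate layer (all-tied closeness 0 cannot occur; guard anyway)
    combined <- combined + .Machine$double.eps
  }
  xi <- topsis_closeness(combined, "benefit", c(w_mean, w_sd))
  rk <- rank_desc(xi)
  attr(rk, "closeness") <- xi
  rk
}

#' Hellinger-TOPSIS ranking of stochastic algorithms
#'
#' Each cell is a Gaussian `N(mu_ij, sigma_ij)`. Per criterion the
#' positive ideal is the (mu, sigma) cell of the alternative with the best
#' mean under the criterion direction and the negative ideal the one with
#' the worst mean. Separations are unweighted sums of Hellinger distances
#' to the ideal cells; closeness is `d- / (d+ + d-)` and alternatives are
#' ranked by descending closeness (ties by ascending index).
#'
#' @param dm a [decision_matrix()] with strictly positive SDs.
#' @return integer rank vector (permutation of `1..L`), with attribute
#'   `closeness`.
#' @export
h_topsis_rank <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  if (any(dm$sd_matrix <= 0)) {
    stop("h_topsis_rank: all sigma_ij must be > 0")
  }
  L <- nrow(dm$mean_matrix); K <- ncol(dm$mean_matrix)
  dpos <- dneg <- numeric(L)
  for (j in seq_len(K)) {
    mu <- dm$mean_matrix[, j]; sg <- dm$sd_matrix[, j]
    ibest <- if (dm$directions[j] == "benefit") which.max(mu) else which.min(mu)
    iworst <- if (dm$directions[j] == "benefit") which.min(mu) else which.max(mu)
    for (i in seq_len(L)) {
      dpos[i] <- dpos[i] +
        hellinger_distance(mu[ibest], sg[ibest], mu[i], sg[i])
      dneg[i] <- dneg[i] +
        hellinger_distance(mu[iworst], sg[iworst], mu[i], sg[i])
    }
  }
  tot <- dpos + dneg
  xi <- ifelse(tot < .Machine$double.eps, 0.5, dneg / tot)
  rk <- rank_desc(xi)
  attr(rk, "closeness") <- as.numeric(xi)
  rk
}
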