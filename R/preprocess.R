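#' Concatenate per-patch feature vectors
#'
#' Histopathology slides are tiled into patches; each patch yields one
#' descriptor vector and the slide-level descriptor is their concatenation
#' in patch order (45 patches x 384 features -> 17280, x 1025 -> 46125).
#'
#' @param patch_vectors list of numeric vectors, all of equal length.
#' @return a single numeric vector of length `sum(lengths(patch_vectors))`.
#' @export
fuse_patch_features <- function(patch_vectors) {
  if (!is.list(patch_vectors) || length(patch_vectors) < 1L) {
    stop("fuse_patch_features: need a non-empty list of patch vectors")
  }
  len <- lengths(patch_vectors)
  if (length(unique(len)) != 1L) {
    stop("fuse_patch_features: patch vectors differ in length (",
         paste(unique(len), collapse = ", "), ")")
  }
  as.numeric(unlist(patch_vectors, use.names = FALSE))
}

#' Locally linear embedding configuration
#'
#' @param n_neighbors neighborhood size k for the local reconstruction.
#' @param n_components target dimension m of the embedding
#'   (`m < k < n_samples` is required).
#' @param regularization ridge added to each local Gram matrix as
#'   `regularization * trace(G) * I`; must be > 0 when neighborhoods
#'   contain duplicated points. Default 1e-3.
#' @param seed integer, kept for interface symmetry; the embedding itself
#'   is deterministic (eigen-sign convention fixes all remaining freedom).
#' @return an object of class `lle_config`.
#' @export
lle_config <- function(n_neighbors = 10L, n_components = 2L,
                       regularization = 1e-3, seed = 1L) {
  cfg <- structure(list(n_neighbors = as.integer(n_neighbors),
                        n_components = as.integer(n_components),
                        regularization = as.numeric(regularization),
                        seed = as.integer(seed)),
                   class = "lle_config")
  if (cfg$regularization < 0) stop("lle_config: regularization must be >= 0")
  if (cfg$n_components >= cfg$n_neighbors) {
    stop("lle_config: n_components (", cfg$n_components,
         ") must be < n_neighbors (", cfg$n_neighbors, ")")
  }
  cfg
}

#' Locally linear embedding of a feature table
#'
#' Standard Roweis-Saul LLE: k-nearest neighbors by Euclidean distance,
#' per-point reconstruction weights solving the regularized local Gram
#' system under a sum-to-one constraint, and the embedding given by the
#' bottom non-constant `m` eigenvectors of `(I-W)'(I-W)`. Labels pass
#' through unchanged. Each embedding component's sign is fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param table a [feature_table()].
#' @param cfg an [lle_config()].
#' @return a [feature_table()] with `n_components` columns `lle0..`,
#'   with an attribute `weights` carrying the n x n reconstruction-weight
#'   matrix (rows sum to 1).
#' @export
lle_embed <- function(table, cfg) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "lle_config"))
  x <- table$features
  n <- nrow(x); k <- cfg$n_neighbors; m <- cfg$n_components
  if (k >= n) stop("lle_embed: n_neighbors (", k, ") must be < n_samples (",
                   n, ")")
  if (m >= n) stop("lle_embed: n_components must be < n_samples")
  if (m > 0.5 * n) {
    warning("lle_embed: n_components close to n_samples degrades the ",
            "embedding quality")
  }
  d2 <- as.matrix(dist(x))^2
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1L)]  # self excluded at rank 1
    z <- sweep(x[nb, , drop = FALSE], 2, x[i, ])
    g <- tcrossprod(z)
    tr <- sum(diag(g))
    if (cfg$regularization > 0) {
      g <- g + diag(cfg$regularization * max(tr, .Machine$double.eps), k)
    }
    wi <- tryCatch(solve(g, rep(1, k)), error = function(e) {
      stop("lle_embed: singular local Gram matrix at sample ", i,
           "; increase `regularization`")
    })
    w[i, nb] <- wi / sum(wi)
  }
  iw <- diag(n) - w
  mmat <- crossprod(iw)
  eg <- eigen(mmat, symmetric = TRUE)
  # bottom eigenvector is the constant mode; take the next m upward
  sel <- seq(n - 1L, by = -1L, length.out = m)
  y <- eg$vectors[, sel, drop = FALSE]
  for (j in seq_len(m)) {
    if (y[which.max(abs(y[, j])), j] < 0) y[, j] <- -y[, j]
  }
  colnames(y) <- paste0("lle", seq_len(m) - 1L)
  out <- feature_table(y, table$labels)
  attr(out, "weights") <- w
  out
}
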