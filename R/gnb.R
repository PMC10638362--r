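#' Fit a Gaussian Naive Bayes classifier
#'
#' Per-class, per-feature Gaussian parameters (mean and maximum-likelihood
#' variance) with class priors taken from class frequencies. A variance
#' floor of `1e-9 * max(feature variances)` keeps constant columns (which
#' occur under aggressive feature masks) well-defined.
#'
#' @param train a [feature_table()] with at least 2 samples per class.
#' @return an object of class `bfox_gnb`.
#' @export
fit_gnb <- function(train) {
  stopifnot(inherits(train, "feature_table"))
  if (n_features(train) < 1L) stop("fit_gnb: need at least one feature")
  cnt <- tabulate(train$labels + 1L, nbins = 2L)
  if (any(cnt < 2L)) stop("fit_gnb: need >= 2 samples in each class")
  x <- train$features
  mu <- var_ <- matrix(0, 2L, ncol(x))
  for (cl in 0:1) {
    xc <- x[train$labels == cl, , drop = FALSE]
    mu[cl + 1L, ] <- colMeans(xc)
    var_[cl + 1L, ] <- colMeans(xc^2) - colMeans(xc)^2  # ML variance
  }
  smoothing <- 1e-9 * max(var_, .Machine$double.eps)
  var_ <- var_ + smoothing
  structure(list(mu = mu, var = var_, prior = cnt / sum(cnt),
                 smoothing = smoothing),
            class = "bfox_gnb")
}

#' Posterior probability of class 1 under a fitted Gaussian Naive Bayes
#'
#' @param object a `bfox_gnb` model.
#' @param newdata numeric matrix (samples x features, same columns as the
#'   training table) or a [feature_table()].
#' @param ... unused.
#' @return numeric vector of `P(class = 1 | x)` in `[0, 1]`.
#' @export
predict.bfox_gnb <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$mu)) {
    stop("predict.bfox_gnb: newdata has ", ncol(newdata),
         " columns, model expects ", ncol(object$mu))
  }
  ll <- vapply(1:2, function(ci) {
    ctr <- sweep(newdata, 2, object$mu[ci, ])
    -0.5 * (ctr^2 %*% (1 / object$var[ci, ]))[, 1L] -
      0.5 * sum(log(2 * pi * object$var[ci, ])) + log(object$prior[ci])
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) ll <- matrix(ll, 1L)
  1 / (1 + exp(ll[, 1L] - ll[, 2L]))
}
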