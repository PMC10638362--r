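#' Multi-objective cost weights
#'
#' Weights of the weighted-sum selection objective
#' `CF = -(a*Acc + b*Fbeta + c*AUC - d*100*(CSF/FSD))`, where Acc, Fbeta
#' and AUC are on the percent scale, CSF is the number of selected features
#' and FSD the total feature count. The weights must sum to 1.
#'
#' @param a,b,c,d non-negative weights for accuracy, F-beta, AUC-ROC and
#'   the selected-feature fraction penalty. Default: equal (0.25 each).
#' @return an object of class `cost_weights`.
#' @export
cost_weights <- function(a = 0.25, b = 0.25, c = 0.25, d = 0.25) {
  w <- structure(list(a = as.numeric(a), b = as.numeric(b),
                      c = as.numeric(c), d = as.numeric(d)),
                 class = "cost_weights")
  if (any(unlist(w) < 0)) stop("cost_weights: weights must be >= 0")
  if (abs(w$a + w$b + w$c + w$d - 1) > 1e-9) {
    stop("cost_weights: a + b + c + d must equal 1 (got ",
         w$a + w$b + w$c + w$d, ")")
  }
  w
}

#' Cross-validation configuration for the wrapper
#'
#' @param n_folds number of stratified folds (default 5).
#' @param oversample duplicate minority rows inside each training fold
#'   until classes balance (default TRUE). Validation folds are never
#'   resampled.
#' @param test_fraction held-out fraction used by [train_test_split()]
#'   callers (default 0.2).
#' @param beta F-measure beta; the default 2 weights recall four times
#'   precision.
#' @param seed integer seed for fold assignment and oversampling.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5L, oversample = TRUE, test_fraction = 0.2,
                      beta = 2, seed = 1L) {
  cfg <- structure(list(n_folds = as.integer(n_folds),
                        oversample = isTRUE(oversample),
                        test_fraction = as.numeric(test_fraction),
                        beta = as.numeric(beta), seed = as.integer(seed)),
                   class = "cv_config")
  if (cfg$n_folds < 2L) stop("cv_config: n_folds must be >= 2")
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 0.5) {
    stop("cv_config: test_fraction must lie in (0, 0.5)")
  }
  cfg
}

#' Balance a table by duplicating minority rows
#'
#' Minority-class rows are duplicated uniformly at random with replacement
#' until the class counts are equal; majority rows are untouched. The row
#' order of the result is shuffled deterministically by `seed`.
#'
#' @param table a [feature_table()] containing both classes.
#' @param seed integer seed.
#' @return a balanced [feature_table()].
#' @export
stratified_oversample <- function(table, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  cnt <- tabulate(table$labels + 1L, nbins = 2L)
  if (any(cnt == 0L)) stop("stratified_oversample: both classes required")
  idx <- local_seed(seed, {
    out <- seq_len(n_samples(table))
    if (cnt[1L] != cnt[2L]) {
      minority <- which(table$labels == (which.min(cnt) - 1L))
      extra <- sample(minority, abs(diff(cnt)), replace = TRUE)
      out <- c(out, extra)
    }
    sample(out)
  })
  ft_rows(table, idx)
}

#' Binary classification metrics on the percent scale
#'
#' Accuracy at a 0.5 score threshold, F-beta from precision and recall of
#' the positive class, and AUC-ROC by the rank (Mann-Whitney) formulation
#' with ties averaged. All three are returned as percentages.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores in `[0, 1]` (class-1 probabilities).
#' @param beta F-measure beta (default 2).
#' @return named list with `accuracy`, `fbeta`, `auc` (percent).
#' @export
compute_metrics <- function(labels, scores, beta = 2) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1), all(scores >= 0 & scores <= 1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("compute_metrics: AUC undefined with a single class")
  }
  pred <- as.integer(scores >= 0.5)
  acc <- mean(pred == labels)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  fb <- if (tp == 0L) 0 else {
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  list(accuracy = 100 * acc, fbeta = 100 * fb, auc = 100 * auc)
}

# deterministic stratified fold assignment (per class, shuffled, round-robin)
make_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  local_seed(seed, {
    for (cl in 0:1) {
      ic <- which(labels == cl)
      if (length(ic) < n_folds) {
        stop("make_folds: class ", cl, " has fewer samples (", length(ic),
             ") than folds (", n_folds, ")")
      }
      folds[sample(ic)] <- rep_len(seq_len(n_folds), length(ic))
    }
  })
  folds
}

#' Evaluate a feature mask by cross-validated Naive Bayes
#'
#' Restricts the table to the masked columns, runs stratified `n_folds`
#' cross-validation with a Gaussian Naive Bayes classifier, applying
#' minority oversampling inside each training fold only (validation folds
#' are untouched), and returns fold-averaged metrics.
#'
#' @param table a [feature_table()] with both classes present.
#' @param mask integer/logical vector of length `n_features` with at least
#'   one active feature.
#' @param cfg a [cv_config()].
#' @return list of class `eval_metrics`: `accuracy`, `fbeta`, `auc`
#'   (percent, fold means), `n_selected`, `n_total`, `inference_time`
#'   (mean seconds to score one validation fold).
#' @export
evaluate_mask <- function(table, mask, cfg = cv_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "cv_config"))
  mask <- as.logical(as.integer(mask))
  if (length(mask) != n_features(table)) {
    stop("evaluate_mask: mask length ", length(mask), " != n_features ",
         n_features(table))
  }
  if (!any(mask)) stop("evaluate_mask: empty mask; repair it first")
  sub <- feature_table(table$features[, mask, drop = FALSE], table$labels)
  folds <- make_folds(sub$labels, cfg$n_folds, cfg$seed)
  acc <- fb <- auc <- tm <- numeric(cfg$n_folds)
  for (f in seq_len(cfg$n_folds)) {
    tr <- ft_rows(sub, which(folds != f))
    va <- ft_rows(sub, which(folds == f))
    if (cfg$oversample) tr <- stratified_oversample(tr, cfg$seed + f)
    model <- fit_gnb(tr)
    t0 <- proc.time()[["elapsed"]]
    sc <- predict(model, va)
    tm[f] <- proc.time()[["elapsed"]] - t0
    m <- compute_metrics(va$labels, sc, cfg$beta)
    acc[f] <- m$accuracy; fb[f] <- m$fbeta; auc[f] <- m$auc
  }
  structure(list(accuracy = mean(acc), fbeta = mean(fb), auc = mean(auc),
                 n_selected = sum(mask), n_total = length(mask),
                 inference_time = mean(tm)),
            class = "eval_metrics")
}

#' Multi-objective selection cost
#'
#' `CF = -(a*Acc + b*Fbeta + c*AUC - d*100*(CSF/FSD))` with the metric
#' terms on the percent scale; lower is better (the selection loop
#' minimizes this).
#'
#' @param m an `eval_metrics` list (see [evaluate_mask()]); any list with
#'   `accuracy`, `fbeta`, `auc`, `n_selected`, `n_total` works.
#' @param w a [cost_weights()].
#' @return scalar cost.
#' @export
cost_function <- function(m, w = cost_weights()) {
  if (!inherits(w, "cost_weights")) stop("cost_function: w must be cost_weights")
  -(w$a * m$accuracy + w$b * m$fbeta + w$c * m$auc -
      w$d * 100 * (m$n_selected / m$n_total))
}
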