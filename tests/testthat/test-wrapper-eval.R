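test_that("cost weights must be a simplex point", {
  expect_error(cost_weights(0.5, 0.5, 0.5, 0.5), "equal 1")
  expect_error(cost_weights(-0.5, 0.5, 0.5, 0.5), ">= 0")
  w <- cost_weights()
  expect_equal(w$a + w$b + w$c + w$d, 1)
})

test_that("cost function matches hand-evaluated cases", {
  m <- list(accuracy = 94.75, fbeta = 93.66, auc = 98.48,
            n_selected = 5, n_total = 200)
  expect_equal(cost_function(m, cost_weights(1, 0, 0, 0)), -94.75)
  expect_equal(cost_function(m, cost_weights(0, 0, 0, 1)), 2.5)
  expect_equal(cost_function(m, cost_weights(0.25, 0.25, 0.25, 0.25)),
               -71.0975)
})

test_that("cost is monotone in each objective", {
  w <- cost_weights()
  base <- list(accuracy = 80, fbeta = 75, auc = 85, n_selected = 10,
               n_total = 50)
  cf0 <- cost_function(base, w)
  for (fld in c("accuracy", "fbeta", "auc")) {
    up <- base; up[[fld]] <- up[[fld]] + 5
    expect_lt(cost_function(up, w), cf0)
  }
  more <- base; more$n_selected <- 20
  expect_gt(cost_function(more, w), cf0)
})

test_that("oversampling balances by duplicating minority rows only", {
  ft <- generate_features(synthetic_spec(100, 4, 1,
                                         minority_fraction = 0.1, seed = 6))
  bal <- stratified_oversample(ft, seed = 2)
  expect_equal(as.integer(table(bal$labels)), c(90L, 90L))
  # every emitted minority row is one of the original minority rows
  orig_min <- ft$features[ft$labels == 1L, , drop = FALSE]
  new_min <- bal$features[bal$labels == 1L, , drop = FALSE]
  keys <- apply(orig_min, 1, paste, collapse = ",")
  expect_true(all(apply(new_min, 1, paste, collapse = ",") %in% keys))
  # majority rows untouched (as a multiset)
  expect_equal(sort(bal$features[bal$labels == 0L, 1]),
               sort(ft$features[ft$labels == 0L, 1]))
  # already balanced input is only reshuffled
  ftb <- generate_features(synthetic_spec(40, 3, 1, seed = 8))
  balb <- stratified_oversample(ftb, seed = 1)
  expect_equal(as.integer(table(balb$labels)), c(20L, 20L))
  expect_equal(sort(balb$features[, 1]), sort(ftb$features[, 1]))
  one_class <- feature_table(matrix(rnorm(10), 5), rep(1, 5))
  expect_error(stratified_oversample(one_class), "both classes")
})

test_that("Gaussian NB recovers priors, midpoint boundary, constant columns", {
  # two well-separated 1-D classes, equal sizes: boundary at the mean midpoint
  x <- matrix(c(rnorm(50, 0, 0.5), rnorm(50, 4, 0.5)))
  ft <- feature_table(x, rep(0:1, each = 50))
  fit <- fit_gnb(ft)
  mid <- mean(fit$mu)
  expect_lt(predict(fit, matrix(mid - 0.5)), 0.5)
  expect_gt(predict(fit, matrix(mid + 0.5)), 0.5)
  # class priors are frequencies
  ft2 <- generate_features(synthetic_spec(100, 3, 1,
                                          minority_fraction = 0.2, seed = 3))
  expect_equal(fit_gnb(ft2)$prior, c(0.8, 0.2))
  # constant feature: variance floored at the smoothing term, finite scores
  ft3 <- feature_table(cbind(rep(1, 20), rnorm(20)), rep(0:1, 10))
  fit3 <- fit_gnb(ft3)
  expect_true(all(is.finite(predict(fit3, ft3$features))))
  expect_equal(fit3$var[1, 1], fit3$smoothing)
})

test_that("Gaussian NB agrees with the e1071 reference classifier", {
  skip_if_not_installed("e1071")
  ft <- generate_features(synthetic_spec(120, 5, 2, effect_size = 1.5,
                                         seed = 17))
  fit <- fit_gnb(ft)
  df <- as.data.frame(ft$features)
  ref <- e1071::naiveBayes(df, factor(ft$labels))
  p_ref <- predict(ref, df, type = "raw")[, "1"]
  p_own <- predict(fit, ft$features)
  expect_equal(as.integer(p_own >= 0.5), as.integer(p_ref >= 0.5))
  # e1071 uses the n-1 variance denominator; probabilities agree closely
  expect_lt(max(abs(p_own - p_ref)), 0.05)
})

test_that("metrics match hand computation and the rank-AUC reference", {
  lab <- c(rep(1, 10), rep(0, 10))
  perfect <- c(rep(1, 10), rep(0, 10))
  m <- compute_metrics(lab, perfect)
  expect_equal(unlist(m), c(accuracy = 100, fbeta = 100, auc = 100))
  # TP=8 FP=2 FN=2 TN=8 at threshold 0.5: precision=recall=0.8, F2=80
  lab2 <- c(rep(1, 8), rep(1, 2), rep(0, 2), rep(0, 8))
  sc2 <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  m2 <- compute_metrics(lab2, sc2, beta = 2)
  expect_equal(m2$fbeta, 80)
  expect_equal(m2$accuracy, 80)
  expect_error(compute_metrics(rep(1, 5), runif(5)), "single class")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(31)
  lab <- rbinom(2000, 1, 0.5)
  sc <- runif(2000)
  expect_lt(abs(compute_metrics(lab, sc)$auc - 50), 3)
})

test_that("rank AUC matches pROC on a tied-score fixture", {
  skip_if_not_installed("pROC")
  set.seed(5)
  lab <- rbinom(200, 1, 0.4)
  sc <- round(runif(200), 1)  # heavy ties
  own <- compute_metrics(lab, sc)$auc / 100
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(own, ref, tolerance = 1e-12)
})

test_that("mask evaluation finds signal, rejects noise, is deterministic", {
  ft <- separable_table(n = 300, d = 10, k = 3, effect = 3)
  cfg <- cv_config(seed = 11)
  all_on <- evaluate_mask(ft, rep(1, 10), cfg)
  expect_gte(all_on$accuracy, 95)
  expect_identical(all_on$n_selected, 10L)
  noise_only <- evaluate_mask(ft, c(rep(0, 3), rep(1, 7)), cfg)
  expect_gt(noise_only$auc, 40)
  expect_lt(noise_only$auc, 60)
  # pure function of (table, mask, cfg)
  again <- evaluate_mask(ft, rep(1, 10), cfg)
  expect_identical(all_on[c("accuracy", "fbeta", "auc")],
                   again[c("accuracy", "fbeta", "auc")])
  expect_error(evaluate_mask(ft, rep(0, 10), cfg), "empty mask")
})

test_that("metrics are invariant to column permutation with matching mask", {
  ft <- separable_table(n = 150, d = 8, k = 2, effect = 2, seed = 14)
  cfg <- cv_config(seed = 4)
  mask <- c(1, 1, 0, 1, 0, 0, 1, 0)
  perm <- c(5, 3, 1, 8, 2, 7, 4, 6)
  ft_p <- feature_table(ft$features[, perm], ft$labels)
  m1 <- evaluate_mask(ft, mask, cfg)
  m2 <- evaluate_mask(ft_p, mask[perm], cfg)
  expect_equal(m1$accuracy, m2$accuracy, tolerance = 1e-9)
  expect_equal(m1$auc, m2$auc, tolerance = 1e-9)
})

test_that("oversampling inside training folds never changes validation data", {
  # on a balanced table the training-fold oversampler is a pure reshuffle,
  # and the Gaussian NB is row-order invariant: metrics must be identical
  ft <- separable_table(n = 200, d = 6, k = 2, effect = 2, seed = 9)
  m_on <- evaluate_mask(ft, rep(1, 6), cv_config(seed = 2, oversample = TRUE))
  m_off <- evaluate_mask(ft, rep(1, 6), cv_config(seed = 2,
                                                  oversample = FALSE))
  expect_equal(m_on$accuracy, m_off$accuracy, tolerance = 1e-9)
  expect_equal(m_on$auc, m_off$auc, tolerance = 1e-9)
})

test_that("the stratified split preserves class shares and partitions rows", {
  ft <- generate_features(synthetic_spec(100, 4, 1,
                                         minority_fraction = 0.3, seed = 12))
  sp <- train_test_split(ft, 0.2, seed = 5)
  expect_equal(n_samples_ <- nrow(sp$train$features) +
                 nrow(sp$test$features), 100)
  expect_equal(as.integer(table(sp$test$labels)), c(14L, 6L))
})
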