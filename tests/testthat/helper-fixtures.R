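# Shared fixtures, all generated in code.

# reference worked examples: H-TOPSIS / A-TOPSIS rank vectors of three
# two-method ranking tables, with the half-integer aggregate scores and
# final ranks they force
ranking_examples <- list(
  ultrasound_deit = list(
    h = c(6, 5, 7, 8, 1, 2, 3, 4),
    a = c(7, 5, 6, 8, 1, 2, 3, 4),
    r_star = c(6.5, 5, 6.5, 8, 1, 2, 3, 4),
    final = c(6, 5, 7, 8, 1, 2, 3, 4)
  ),
  ultrasound_swin = list(
    h = c(4, 6, 8, 7, 2, 5, 3, 1),
    a = c(3, 6, 8, 7, 1, 5, 4, 2),
    r_star = c(3.5, 6, 8, 7, 1.5, 5, 3.5, 1.5),
    final = c(3, 6, 8, 7, 1, 5, 4, 2)
  ),
  histo_swin = list(
    h = c(4, 6, 8, 7, 2, 5, 3, 1),
    a = c(6, 1, 8, 7, 3, 4, 2, 5),
    r_star = c(5, 3.5, 8, 7, 2.5, 4.5, 2.5, 3),
    final = c(6, 4, 8, 7, 1, 5, 2, 3)
  )
)

# strongly separable two-class table for wrapper sanity checks
separable_table <- function(n = 300, d = 10, k = 3, effect = 3, seed = 21) {
  generate_features(synthetic_spec(n, d, k, effect_size = effect,
                                   seed = seed))
}

# n points on an isotropic 2-D plane rotated into 10-D
plane_table <- function(n = 200, seed = 42) {
  set.seed(seed)
  z <- cbind(runif(n, 0, 3), runif(n, 0, 3))
  rot <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  feature_table(z %*% t(rot), rep(0:1, length.out = n))
}

# per-column rank AUC (independent of compute_metrics)
column_auc <- function(xcol, lab) {
  r <- rank(xcol)
  n1 <- sum(lab == 1L)
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * sum(lab == 0L))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
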