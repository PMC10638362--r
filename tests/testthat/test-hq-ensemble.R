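test_that("identical rankings are a fixed point with uniform weights", {
  r <- c(2, 1, 4, 3)
  agg <- hq_aggregate(list(r, r, r))
  expect_equal(agg$s_star, r)
  expect_equal(agg$weights, rep(1 / 3, 3))
  expect_equal(consensus_index(list(r, r, r), agg$s_star), 1)
})

test_that("two rankings aggregate to their exact elementwise midpoint", {
  for (ex in ranking_examples) {
    agg <- hq_aggregate(list(ex$h, ex$a))
    expect_equal(agg$s_star, (ex$h + ex$a) / 2)
    expect_equal(agg$s_star, ex$r_star)
    expect_identical(agg$final_ranks, as.integer(ex$final))
  }
  expect_error(hq_aggregate(list(c(1, 2))), ">= 2")
  expect_error(hq_aggregate(list(c(1, 2), c(1, 2, 3))), "length")
})

test_that("aggregation downweights an outlier ranking", {
  rks <- list(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  agg <- hq_aggregate(rks, aggregation_config(kernel_sigma_mode = "fixed",
                                              kernel_sigma = 2))
  mean_s <- colMeans(do.call(rbind, rks))
  d_agg <- sqrt(sum((agg$s_star - c(1, 2, 3))^2))
  d_mean <- sqrt(sum((mean_s - c(1, 2, 3))^2))
  expect_lt(d_agg, d_mean)
  expect_lt(agg$weights[3], agg$weights[1])
})

test_that("the aggregate matches a dense grid search of the HQ objective", {
  sig <- 2
  cfg <- aggregation_config(kernel_sigma_mode = "fixed", kernel_sigma = sig)
  rks <- list(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  agg <- hq_aggregate(rks, cfg)
  welsch_obj <- function(s_star) {
    0.5 * sum(vapply(rks, function(r) {
      sig^2 * (1 - exp(-sum((r - s_star)^2) / (2 * sig^2)))
    }, numeric(1)))
  }
  grid <- seq(0.5, 3.5, by = 0.01)
  best <- c(Inf, NA, NA)
  for (k1 in grid) for (k3 in grid) {
    o <- welsch_obj(c(k1, 2, k3))
    if (o < best[1]) best <- c(o, k1, k3)
  }
  expect_equal(agg$s_star[c(1, 3)], best[2:3], tolerance = 0.011)
  expect_lte(welsch_obj(agg$s_star), best[1] + 1e-9)
})

test_that("the fixed-sigma surrogate objective descends each iteration", {
  set.seed(17)
  rks <- lapply(1:4, function(i) sample(6))
  agg <- hq_aggregate(rks, aggregation_config(kernel_sigma_mode = "fixed",
                                              kernel_sigma = 3))
  expect_true(all(diff(agg$objective) <= 1e-10))
})

test_that("the aggregate lies in the elementwise convex hull of the inputs", {
  set.seed(23)
  for (i in 1:10) {
    rks <- lapply(1:3, function(j) sample(5))
    s <- do.call(rbind, rks)
    agg <- hq_aggregate(rks)
    expect_true(all(agg$s_star >= apply(s, 2, min) - 1e-9))
    expect_true(all(agg$s_star <= apply(s, 2, max) + 1e-9))
  }
})

test_that("consensus index evaluates the Gaussian kernel agreement", {
  ex <- ranking_examples$ultrasound_deit
  rks <- list(ex$h, ex$a)
  agg <- hq_aggregate(rks)
  # the two rankings disagree at two positions by one rank each; with
  # sigma = 1 each of the four affected cells contributes exp(-1/8)
  expect_equal(consensus_index(rks, agg$s_star),
               (12 + 4 * exp(-0.125)) / 16)
  q_all <- exp(-(do.call(rbind, rks) -
                   matrix(agg$s_star, 2, 8, byrow = TRUE))^2 / 2)
  expect_true(all(q_all > 0 & q_all <= 1))
})

test_that("trust equals consensus under uniform weights", {
  set.seed(41)
  for (i in 1:5) {
    rks <- lapply(1:2, function(j) sample(8))
    agg <- hq_aggregate(rks)
    # N = 2: symmetric residuals force uniform weights
    expect_equal(agg$weights, c(0.5, 0.5))
    expect_equal(trust_level(rks, agg$s_star, agg$weights),
                 consensus_index(rks, agg$s_star))
  }
  # a unit-weight ranking agreeing perfectly with the aggregate
  r <- c(3, 1, 2)
  expect_equal(trust_level(list(r, c(9, 9, 9)), r, c(1, 0)), 1)
  expect_error(trust_level(list(r, r), r, c(0.7, 0.6)), "sum to 1")
})

test_that("downweighting an outlier raises trust above consensus", {
  rks <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1))
  agg <- hq_aggregate(rks, aggregation_config(kernel_sigma_mode = "fixed",
                                              kernel_sigma = 1.5))
  expect_gt(trust_level(rks, agg$s_star, agg$weights),
            consensus_index(rks, agg$s_star))
})

test_that("final ranks order ascending scores with index tie-break", {
  expect_identical(final_ranks(c(6.5, 5, 6.5, 8, 1, 2, 3, 4)),
                   c(6L, 5L, 7L, 8L, 1L, 2L, 3L, 4L))
  ex2 <- ranking_examples$ultrasound_swin
  expect_identical(final_ranks(ex2$r_star), as.integer(ex2$final))
  # idempotent under strictly increasing transforms
  s <- c(2.5, 1.5, 9, 0.1, 2.5)
  expect_identical(final_ranks(s), final_ranks(exp(s)))
  set.seed(3)
  x <- rnorm(10)
  expect_setequal(final_ranks(x), 1:10)
  expect_identical(final_ranks(sort(x))[1], 1L)
  expect_error(final_ranks(c(1, NaN)), "non-finite")
})

test_that("the benchmark table reproduces the reference rank-aggregation rows", {
  ex <- ranking_examples$histo_swin
  br <- run_benchmark(rank_matrix = rbind(ex$h, ex$a),
                      labels = c(paste0("s", 1:4), paste0("v", 1:4)))
  expect_equal(br$table$r_star, ex$r_star)
  expect_identical(br$table$final_rank, as.integer(ex$final))
  expect_equal(br$consensus, br$trust)  # two methods -> uniform weights
  expect_setequal(br$table$final_rank, 1:8)
})

test_that("a dominant variant is ranked first by the full stack", {
  mk_stats <- function(acc, f2, auc, nsel, sdv, tf) {
    structure(list(stats = data.frame(
      metric = c("accuracy", "f2", "auc", "n_selected"),
      mean = c(acc, f2, auc, nsel),
      sd = rep(sdv, 4)), n_runs = 5L, transfer = tf),
      class = "run_statistics")
  }
  stats <- list(mk_stats(95, 94, 98, 4, 0.2, "v1"),
                mk_stats(88, 86, 90, 9, 0.8, "s1"),
                mk_stats(85, 84, 88, 12, 1.0, "s2"))
  br <- run_benchmark(stats)
  expect_identical(br$table$final_rank[1], 1L)
  expect_identical(br$table$variant[1], "v1")
  expect_equal(nrow(br$table), 3L)
  # csv emission carries the footers
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranking_csv(br, path)
  tail2 <- utils::tail(readLines(path), 2)
  expect_match(tail2[1], "^consensus,")
  expect_match(tail2[2], "^trust,")
})
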