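#' Binary FOX optimizer configuration
#'
#' The FOX metaheuristic mimics a red fox hunting by sound: in the
#' exploitation phase the fox estimates the distance to the prey from the
#' returning sound and executes a gravity-based jump; in the exploration
#' phase it searches around the best position under a decaying schedule.
#' Continuous positions are binarized per iteration by the configured
#' transfer function.
#'
#' @param transfer a [transfer_function()] or its name (`"s1".."v4"`).
#' @param n_agents population size (default 30).
#' @param n_iterations iterations/epochs (default 100).
#' @param bounds length-2 numeric, continuous search interval
#'   (default `c(-1, 1)`).
#' @param s_orientation S-family binarization orientation, see
#'   [binarize_s()].
#' @param weights a [cost_weights()].
#' @param cv a [cv_config()] used by the wrapper fitness.
#' @param seed integer seed for the optimizer stream.
#' @return an object of class `fox_config`.
#' @export
fox_config <- function(transfer = "v1", n_agents = 30L, n_iterations = 100L,
                       bounds = c(-1, 1),
                       s_orientation = c("as_printed", "conventional"),
                       weights = cost_weights(), cv = cv_config(),
                       seed = 1L) {
  if (!inherits(transfer, "transfer_function")) {
    transfer <- transfer_function(transfer)
  }
  s_orientation <- match.arg(s_orientation)
  cfg <- structure(list(transfer = transfer,
                        n_agents = as.integer(n_agents),
                        n_iterations = as.integer(n_iterations),
                        bounds = as.numeric(bounds),
                        s_orientation = s_orientation,
                        weights = weights, cv = cv,
                        seed = as.integer(seed)),
                   class = "fox_config")
  if (cfg$n_agents < 2L) stop("fox_config: n_agents must be >= 2")
  if (cfg$n_iterations < 1L) stop("fox_config: n_iterations must be >= 1")
  if (cfg$bounds[1L] >= cfg$bounds[2L]) {
    stop("fox_config: bounds must satisfy low < high")
  }
  cfg
}

# FOX dynamics constants (jump coefficients, gravity, phase thresholds)
FOX_C1 <- 0.18
FOX_C2 <- 0.82
FOX_GRAVITY <- 9.81

# memoizing wrapper-fitness closure: masks recur across agents/iterations
make_cost_evaluator <- function(table, cfg) {
  cache <- new.env(parent = emptyenv())
  function(bits) {
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    m <- evaluate_mask(table, bits, cfg$cv)
    res <- list(metrics = m, cost = cost_function(m, cfg$weights))
    cache[[key]] <- res
    res
  }
}

fox_init_state <- function(table, cfg, evaluator) {
  d <- n_features(table)
  cont <- matrix(runif(cfg$n_agents * d, cfg$bounds[1L], cfg$bounds[2L]),
                 cfg$n_agents, d)
  bin <- matrix(0L, cfg$n_agents, d)
  costs <- numeric(cfg$n_agents)
  for (i in seq_len(cfg$n_agents)) {
    bin[i, ] <- repair_mask(rbinom(d, 1L, 0.5))
    costs[i] <- evaluator(bin[i, ])$cost
  }
  best <- which.min(costs)
  structure(list(continuous_positions = cont, binary_positions = bin,
                 agent_costs = costs,
                 best_binary = bin[best, ], best_continuous = cont[best, ],
                 best_cost = costs[best], iteration = 0L,
                 min_time_avg = mean(runif(d))),
            class = "fox_state")
}

#' One iteration of the binary FOX search
#'
#' Each agent draws a phase variable r ~ U(0,1). Exploitation (r >= 0.5):
#' per-dimension sound travel times t ~ U(0,1); the distance to the prey is
#' half the best continuous position (sound travels there and back); the
#' jump is `0.5 * 9.81 * (mean(t)/2)^2` and the new position is
#' `distance * jump * c` with c = 0.18 if a second uniform exceeds 0.18,
#' else 0.82. Exploration (r < 0.5): position = best continuous position
#' times U(0,1)^d times the minimum observed mean travel time times
#' `a = 2 (1 - u / n_iterations)`. Positions are clamped to the bounds,
#' binarized by the configured transfer function, repaired, and evaluated;
#' the best-so-far is elitist (ties keep the first incumbent).
#'
#' @param state a `fox_state` (see [fox_optimize()]).
#' @param cfg a [fox_config()].
#' @param evaluator internal memoized cost evaluator; created automatically
#'   by [fox_optimize()].
#' @return the advanced `fox_state`.
#' @export
fox_step <- function(state, cfg, evaluator) {
  stopifnot(inherits(state, "fox_state"), inherits(cfg, "fox_config"))
  d <- ncol(state$continuous_positions)
  u <- state$iteration + 1L
  a_sched <- 2 * (1 - u / cfg$n_iterations)
  for (i in seq_len(cfg$n_agents)) {
    r <- runif(1)
    tt_dims <- runif(d)
    tt <- mean(tt_dims)
    if (r >= 0.5) {
      dist_prey <- 0.5 * state$best_continuous
      jump <- 0.5 * FOX_GRAVITY * (tt / 2)^2
      p <- runif(1)
      cc <- if (p > 0.18) FOX_C1 else FOX_C2
      newpos <- dist_prey * jump * cc
    } else {
      newpos <- state$best_continuous * runif(d) * state$min_time_avg * a_sched
    }
    state$min_time_avg <- min(state$min_time_avg, tt)
    newpos <- pmin(pmax(newpos, cfg$bounds[1L]), cfg$bounds[2L])
    state$continuous_positions[i, ] <- newpos
    bits <- if (cfg$transfer$family == "S") {
      binarize_s(newpos, cfg$transfer, cfg$s_orientation)
    } else {
      binarize_v(newpos, state$binary_positions[i, ], cfg$transfer)
    }
    bits <- repair_mask(bits)
    state$binary_positions[i, ] <- bits
    cost <- tryCatch(evaluator(bits)$cost, error = function(e) {
      stop("fox_step: cost evaluation failed for agent ", i, ": ",
           conditionMessage(e))
    })
    state$agent_costs[i] <- cost
    if (cost < state$best_cost) {
      state$best_cost <- cost
      state$best_binary <- bits
      state$best_continuous <- newpos
    }
  }
  state$iteration <- u
  state
}

#' Run the binary FOX wrapper feature selection
#'
#' Initializes continuous positions uniformly in the bounds and binary
#' positions as Bernoulli(0.5) masks (repaired to be non-empty), then runs
#' `n_iterations` of [fox_step()]. Fitness is the multi-objective cost of
#' [cost_function()] over cross-validated Naive Bayes metrics
#' ([evaluate_mask()]).
#'
#' @param table a [feature_table()].
#' @param cfg a [fox_config()].
#' @return object of class `fox_result`: `best_mask` (integer 0/1),
#'   `best_cost`, `cost_history` (length `n_iterations`, non-increasing),
#'   `metrics` (the `eval_metrics` of the best mask), `elapsed_time`
#'   (seconds), `transfer` (variant name), `seed`.
#' @examples
#' ft <- generate_features(synthetic_spec(60, 6, 2, effect_size = 2,
#'                                        seed = 3))
#' res <- fox_optimize(ft, fox_config("v1", n_agents = 5, n_iterations = 5,
#'                                    seed = 3))
#' res$best_cost
#' @export
fox_optimize <- function(table, cfg) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "fox_config"))
  t0 <- proc.time()[["elapsed"]]
  evaluator <- make_cost_evaluator(table, cfg)
  history <- numeric(cfg$n_iterations)
  state <- local_seed(cfg$seed, {
    st <- fox_init_state(table, cfg, evaluator)
    for (u in seq_len(cfg$n_iterations)) {
      st <- fox_step(st, cfg, evaluator)
      history[u] <- st$best_cost
    }
    st
  })
  structure(list(best_mask = state$best_binary,
                 best_cost = state$best_cost,
                 cost_history = history,
                 metrics = evaluator(state$best_binary)$metrics,
                 elapsed_time = proc.time()[["elapsed"]] - t0,
                 transfer = cfg$transfer$name,
                 seed = cfg$seed),
            class = "fox_result")
}

#' @export
print.fox_result <- function(x, ...) {
  cat("fox_result [", toupper(x$transfer), "]: best cost ",
      format(x$best_cost, digits = 6), ", ", x$metrics$n_selected, "/",
      x$metrics$n_total, " features selected\n", sep = "")
  invisible(x)
}

#' Exhaustive wrapper search over all non-empty masks
#'
#' Brute-force oracle for small feature counts: evaluates every non-empty
#' feature subset and returns the minimum-cost mask. Intended for
#' validating the metaheuristic (its best cost can never beat this bound).
#'
#' @param table a [feature_table()] with at most `max_features` columns.
#' @param weights a [cost_weights()].
#' @param cv a [cv_config()].
#' @param max_features safety cap (default 12).
#' @return list with `best_mask`, `best_cost`, and `costs` (one entry per
#'   mask, names encoding the bits).
#' @export
exhaustive_mask_search <- function(table, weights = cost_weights(),
                                   cv = cv_config(), max_features = 12L) {
  d <- n_features(table)
  if (d > max_features) {
    stop("exhaustive_mask_search: ", d, " features exceed max_features = ",
         max_features)
  }
  costs <- numeric(2^d - 1L)
  names_ <- character(2^d - 1L)
  best_cost <- Inf; best_mask <- NULL
  for (code in seq_len(2^d - 1L)) {
    bits <- as.integer(bitwAnd(bitwShiftR(code, seq_len(d) - 1L), 1L))
    m <- evaluate_mask(table, bits, cv)
    cst <- cost_function(m, weights)
    costs[code] <- cst
    names_[code] <- paste(bits, collapse = "")
    if (cst < best_cost) { best_cost <- cst; best_mask <- bits }
  }
  names(costs) <- names_
  list(best_mask = best_mask, best_cost = best_cost, costs = costs)
}

#' Multi-run statistics for one selector variant
#'
#' Runs [fox_optimize()] `n_runs` times with seeds `seed + 0 .. n_runs-1`
#' and reports the per-metric mean and sample SD (n-1 denominator) over
#' runs, the summary the ranking stack consumes.
#'
#' @param table a [feature_table()].
#' @param cfg a [fox_config()]; its `seed` is the base seed.
#' @param n_runs number of repeats (>= 2; the study protocol uses 30).
#' @return object of class `run_statistics`: data.frame `stats` with
#'   columns `metric`, `mean`, `sd` over the metrics accuracy, f2, auc,
#'   inference_time, n_selected, cost, elapsed_time; plus `n_runs` and
#'   `transfer`.
#' @export
multi_run_stats <- function(table, cfg, n_runs = 30L) {
  if (n_runs < 2L) stop("multi_run_stats: n_runs must be >= 2")
  runs <- lapply(seq_len(n_runs) - 1L, function(off) {
    cfg$seed <- cfg$seed + off
    fox_optimize(table, cfg)
  })
  pull <- function(f) vapply(runs, f, numeric(1))
  vals <- list(accuracy = pull(function(r) r$metrics$accuracy),
               f2 = pull(function(r) r$metrics$fbeta),
               auc = pull(function(r) r$metrics$auc),
               inference_time = pull(function(r) r$metrics$inference_time),
               n_selected = pull(function(r) r$metrics$n_selected),
               cost = pull(function(r) r$best_cost),
               elapsed_time = pull(function(r) r$elapsed_time))
  stats <- data.frame(metric = names(vals),
                      mean = vapply(vals, mean, numeric(1)),
                      sd = vapply(vals, sd, numeric(1)),
                      row.names = NULL)
  structure(list(stats = stats, n_runs = as.integer(n_runs),
                 transfer = cfg$transfer$name, runs = runs),
            class = "run_statistics")
}

#' @export
print.run_statistics <- function(x, ...) {
  cat("run_statistics [", toupper(x$transfer), "], ", x$n_runs, " runs:\n",
      sep = "")
  print(x$stats, digits = 5)
  invisible(x)
}
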