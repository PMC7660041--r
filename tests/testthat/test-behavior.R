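test_that("compute_rmse matches closed forms and hand-computed oracle", {
  blk <- function(err) list(target_deg = rep(0, length(err)), wrist_deg = err)
  expect_identical(compute_rmse(blk(c(0, 0, 0, 0))), 0)
  expect_equal(compute_rmse(blk(rep(3, 10))), 3)
  expect_equal(compute_rmse(blk(c(1, -1, 2, -2))), sqrt(10 / 4))
  expect_error(compute_rmse(list(target_deg = 1, wrist_deg = 1)), "length")
})

test_that("RMSE is invariant to trace exchange and common offsets", {
  set.seed(5)
  for (rep in 1:5) {
    target <- cumsum(rnorm(50))
    wrist <- target + rnorm(50)
    r1 <- compute_rmse(list(target_deg = target, wrist_deg = wrist))
    r2 <- compute_rmse(list(target_deg = wrist, wrist_deg = target))
    r3 <- compute_rmse(list(target_deg = target + 7, wrist_deg = wrist + 7))
    expect_equal(r1, r2)
    expect_equal(r1, r3)
  }
})

test_that("corrected endpoints reproduce exact and least-squares oracles", {
  expect_equal(corrected_endpoints(rep(4.2, 9)), c(start = 4.2, end = 4.2))
  ep <- corrected_endpoints(c(10, 9, 8, 7, 6, 5.5, 5.2, 5.4, 5.1, 5.0))
  expect_equal(ep[["start"]], 10)
  series <- c(10, 9, 9, 7, 6)
  ep5 <- corrected_endpoints(series)
  expect_equal(ep5[["start"]], ols_at(1:5, series, 1), tolerance = 1e-12)
  expect_equal(ep5[["end"]], ols_at(1:5, series, 5), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:10) {
    y <- 8 + rnorm(12)
    ep12 <- corrected_endpoints(y)
    expect_equal(ep12[["start"]], ols_at(1:5, y[1:5], 1), tolerance = 1e-12)
    expect_equal(ep12[["end"]], ols_at(8:12, y[8:12], 12), tolerance = 1e-12)
  }
  expect_error(corrected_endpoints(c(1, 2, 3), session = "retest1"), "retest1")
})

test_that("endpoint estimates are linear in the RMSE series", {
  set.seed(13)
  y <- 9 + rnorm(10)
  for (k in c(0.5, 2, 10)) {
    expect_equal(corrected_endpoints(k * y), k * corrected_endpoints(y),
                 tolerance = 1e-12)
  }
})

test_that("delta_performance signs, percentages and arithmetic oracle", {
  tl <- list(endpoints = tibble::tibble(
    sequence_type = "repeated",
    T0 = 10, T1 = 9.5, T2 = 8.9, T3 = 8, T4 = 8.8, T5 = 8.6))
  d <- delta_performance(tl)
  get <- function(p) d$delta_deg[d$pair == p]
  expect_equal(get("T0-T2"), 1.1)
  expect_equal(d$delta_pct[d$pair == "T0-T2"], 11)
  expect_equal(get("T3-T4"), -0.8)           # overnight forgetting
  expect_equal(d$delta_pct[d$pair == "T3-T4"], -8)
  tl0 <- list(endpoints = tibble::tibble(
    sequence_type = "repeated", T0 = 8, T1 = 8, T2 = 8, T3 = 8, T4 = 8, T5 = 8))
  expect_true(all(delta_performance(tl0)$delta_deg == 0))
  tl_bad <- list(endpoints = tibble::tibble(sequence_type = "repeated", T0 = 8))
  expect_error(delta_performance(tl_bad), "missing endpoints")
})

test_that("performance_timeline scores a whole subject consistently", {
  bp <- quiet_bp()
  blocks <- c(
    simulate_tracking_session(bp, 40, "training", 0, seed = 21),
    simulate_tracking_session(bp, 5, "retest1", 40, seed = 22),
    simulate_tracking_session(bp, 10, "retest2", 45, seed = 23))
  tl <- performance_timeline(blocks)
  expect_setequal(tl$endpoints$sequence_type, c("repeated", "random"))
  expect_equal(nrow(tl$rmse), 2 * (40 + 5 + 10))
  # noise-free: T0 equals the learning-curve value at block 1 (linear fit of
  # a near-linear 5-block segment, so close to the closed form)
  t0 <- tl$endpoints$T0[tl$endpoints$sequence_type == "repeated"]
  expect_equal(t0, learning_curve(bp, 1, "repeated", "training"),
               tolerance = 0.01)
  # retest1 has 5 blocks: T2 and T3 come from one fitted line
  rm5 <- tl$rmse[tl$rmse$session == "retest1" &
                   tl$rmse$sequence_type == "repeated", ]
  ep <- corrected_endpoints(rm5$rmse[order(rm5$block)])
  expect_equal(tl$endpoints$T2[tl$endpoints$sequence_type == "repeated"],
               ep[["start"]])
  expect_equal(tl$endpoints$T3[tl$endpoints$sequence_type == "repeated"],
               ep[["end"]])
})

test_that("no-learning cohorts show near-zero mean training delta", {
  bp <- behavior_params(learning_amplitude = 0, noise_sd = 0.3,
                        fatigue_slope = 0, offline_boost = 0,
                        overnight_forgetting = 0)
  deltas <- vapply(1:120, function(i) {
    blocks <- c(simulate_tracking_session(bp, 40, "training", 0,
                                          seed = 500 + i),
                simulate_tracking_session(bp, 5, "retest1", 40,
                                          seed = 9500 + i),
                simulate_tracking_session(bp, 10, "retest2", 45,
                                          seed = 18500 + i))
    tl <- performance_timeline(blocks)
    d <- delta_performance(tl)
    d$delta_deg[d$pair == "T0-T1" & d$sequence_type == "repeated"]
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.1)
})
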