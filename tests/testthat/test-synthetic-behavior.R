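test_that("seeded cohorts are reproduced exactly", {
  spec <- tiny_cohort_spec(seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$osc, c2$osc)
  expect_identical(c1$behavior, c2$behavior)
  ep1 <- subject_epochs(c1, "p01", "Post1")
  ep2 <- subject_epochs(c2, "p01", "Post1")
  expect_identical(ep1$data, ep2$data)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(sessions = c("Pre", "Pre", "Post1")), "unique")
  expect_error(behavior_params(initial_rmse = -1), "initial_rmse")
  expect_error(behavior_params(noise_sd = -0.1), "noise_sd")
  expect_error(behavior_params(offline_boost = 1.5), "offline_boost")
  expect_error(oscillation_params(beta_freq = 8), "beta_freq")
  expect_error(oscillation_params(mrbd_depth = 0.2), "mrbd_depth")
})

test_that("noise-free curves follow the closed-form learning function", {
  bp <- quiet_bp()
  blocks <- simulate_tracking_session(bp, 12, "training", 0, seed = 31)
  for (b in blocks) {
    # independent evaluation of the generator's mean function
    amp <- bp$learning_amplitude *
      (1 + ifelse(b$sequence_type == "repeated", bp$sequence_gain, 0))
    expected <- bp$initial_rmse - amp * (1 - exp(-bp$learning_rate * b$block_index))
    expect_equal(compute_rmse(b), expected, tolerance = 1e-10)
  }
})

test_that("zero-error traces make wrist equal target", {
  bp <- behavior_params(initial_rmse = 1e-9, noise_sd = 0)
  blocks <- simulate_tracking_session(bp, 2, seed = 1)
  # sigma floors at 0.05 deg; check the trace equals target + tiny error
  expect_lt(max(abs(blocks[[1]]$wrist_deg - blocks[[1]]$target_deg)), 0.5)
  # learning_amplitude = 0: expected RMSE constant across blocks
  bp0 <- behavior_params(learning_amplitude = 0, noise_sd = 0,
                         fatigue_slope = 0)
  rs <- vapply(simulate_tracking_session(bp0, 10, seed = 2), compute_rmse,
               numeric(1))
  expect_equal(max(rs) - min(rs), 0, tolerance = 1e-9)
})

test_that("sequence-specific learning emerges from mid-training on", {
  bp <- behavior_params(noise_sd = 0.3)
  diffs <- replicate(100, {
    blocks <- simulate_tracking_session(bp, 40, "training", 0,
                                        seed = sample.int(1e6, 1))
    rm <- vapply(blocks, compute_rmse, numeric(1))
    seqt <- vapply(blocks, `[[`, "", "sequence_type")
    idx <- vapply(blocks, `[[`, 0L, "block_index")
    late <- idx > 20
    mean(rm[late & seqt == "random"]) - mean(rm[late & seqt == "repeated"])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("the planted effect lands in the cohort tables as specified", {
  spec <- tiny_cohort_spec(seed = 77)
  ch <- generate_cohort(spec)
  gt <- ch$ground_truth$latents
  # retest2 shift contains slope * z_pred; regress shift on the latents
  fit <- lm(gt$shift_retest2_deg ~ gt$z_planted_predictor + gt$ability)
  pe <- spec$prediction_effect
  expect_equal(unname(coef(fit)[2]), pe$slope * pe$scale_deg, tolerance = 0.35)
  expect_equal(unname(coef(fit)[3]),
               pe$confounds[["prior_performance"]] * pe$scale_deg,
               tolerance = 0.35)
  # predictor must reference an existing table entry
  expect_error(
    generate_cohort(tiny_cohort_spec(
      prediction_effect = planted_effect(predictor = "pmbr_contralateral_PostX"))),
    "session")
  expect_error(
    generate_cohort(tiny_cohort_spec(
      prediction_effect = planted_effect(target = "T9"))),
    "target")
})

test_that("learning-curve parameters are recoverable from simulated sessions", {
  bp <- behavior_params(noise_sd = 0.3)
  set.seed(99)
  # 200 sessions, random-sequence blocks only (no sequence gain term)
  rmse_mat <- vapply(1:200, function(i) {
    blocks <- simulate_tracking_session(bp, 40, "training", 0,
                                        seed = 7000 + i)
    rm <- vapply(blocks, compute_rmse, numeric(1))
    seqt <- vapply(blocks, `[[`, "", "sequence_type")
    rm[seqt == "random"]
  }, numeric(40))
  avg <- rowMeans(rmse_mat)
  b <- 1:40
  fat <- bp$fatigue_slope * pmax(0, b - bp$fatigue_onset)
  fit <- stats::nls(avg ~ i0 - A * (1 - exp(-r * b)) + fat,
                    start = list(i0 = 9, A = 1, r = 0.2))
  est <- coef(fit)
  expect_equal(unname(est["A"]), bp$learning_amplitude, tolerance = 0.1)
  expect_equal(unname(est["r"]), bp$learning_rate, tolerance = 0.1)
})
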