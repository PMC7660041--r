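make_rec <- function(fun, channels = c("C3", "C4"), fs = 600, secs = 30,
                     onsets = NULL) {
  n <- fs * secs
  t <- (seq_len(n) - 1) / fs
  sig <- do.call(rbind, lapply(seq_along(channels), function(i) fun(t, i)))
  if (is.null(onsets)) onsets <- round(c(5, 15) * fs)
  eeg_recording(sig, channels, fs,
                tibble::tibble(onset_sample = onsets,
                               condition = rep_len(c("flexion", "extension"),
                                                   length(onsets))))
}

test_that("average reference removes a common offset exactly", {
  # identical constant channels: the common offset is the cross-channel
  # mean, so average referencing zeroes the signal exactly
  rec <- make_rec(function(t, i) rep(10, length(t)))
  out <- preprocess(rec, target_fs = 300)
  expect_lt(max(abs(out$signal)), 1e-6)
  # a shared offset on top of channel-specific signals also vanishes
  rec2 <- make_rec(function(t, i) (-1)^i * sin(2 * pi * 20 * t) + 7)
  rec3 <- make_rec(function(t, i) (-1)^i * sin(2 * pi * 20 * t))
  out2 <- preprocess(rec2, target_fs = 300)
  out3 <- preprocess(rec3, target_fs = 300)
  expect_equal(out2$signal, out3$signal, tolerance = 1e-9)
})

test_that("the notch suppresses 50 Hz by at least 20 dB, passband intact", {
  # antisymmetric channels survive average referencing
  rec50 <- make_rec(function(t, i) (-1)^i * sin(2 * pi * 50 * t))
  out50 <- preprocess(rec50, target_fs = 300)
  mid <- 3000:6000
  rms_in <- sqrt(mean(rec50$signal[1, mid * 2]^2))
  rms_out <- sqrt(mean(out50$signal[1, mid]^2))
  expect_lt(20 * log10(rms_out / rms_in), -20)

  rec10 <- make_rec(function(t, i) (-1)^i * sin(2 * pi * 10 * t))
  out10 <- preprocess(rec10, target_fs = 300)
  amp_out <- sqrt(2 * mean(out10$signal[1, mid]^2))
  expect_equal(amp_out, 1, tolerance = 0.05)
})

test_that("preprocessing remaps events and validates pools and rate", {
  rec <- make_rec(function(t, i) (-1)^i * sin(2 * pi * 20 * t))
  out <- preprocess(rec, target_fs = 300)
  expect_equal(out$fs, 300)
  expect_equal(out$events$onset_sample,
               round((rec$events$onset_sample - 1) * 300 / 600) + 1)
  expect_error(preprocess(rec, pools = electrode_pools()), "CP1")
  slow <- make_rec(function(t, i) t, fs = 150, secs = 10,
                   onsets = c(150, 300))
  expect_error(preprocess(slow), "200 Hz")
})

test_that("epoching cuts the window and rejection drops the spiked trial", {
  fs <- 300
  # spacing > epoch length so the spike lands in exactly one trial
  onsets <- round(c(3, 14, 25, 36) * fs)
  rec <- make_rec(function(t, i) sin(2 * pi * 20 * t), fs = fs, secs = 50,
                  onsets = onsets)
  ep <- epoch_and_reject(rec, window = c(-1, 9), threshold = Inf)
  expect_equal(ep$retained, 1:4)
  expect_equal(dim(ep$data)[3], 3000)
  # inject a 10x spike into trial 3 only
  rec2 <- rec
  rec2$signal[1, onsets[3] + 150] <- 20
  ep2 <- epoch_and_reject(rec2, window = c(-1, 9), threshold = 10)
  expect_equal(ep2$retained, c(1, 2, 4))
  expect_error(epoch_and_reject(rec2, window = c(-1, 9), threshold = 0.1),
               "all trials rejected")
  # event too close to the record start for a -1 s window
  rec3 <- make_rec(function(t, i) t * 0, fs = fs, secs = 50,
                   onsets = c(round(0.5 * fs), round(20 * fs)))
  expect_error(epoch_and_reject(rec3, window = c(-1, 9)), "does not fit")
})

test_that("morlet power: zero input, quadratic scaling, chirp ridge", {
  zero <- manual_epochs(function(t) matrix(0, 1, length(t)), 1, "C3", 300)
  tfz <- morlet_power(zero, freqs = c(10, 20, 30))
  expect_true(all(tfz$power == 0))

  sine <- function(a) manual_epochs(function(t) {
    matrix(a * sin(2 * pi * 20 * t), 1, length(t))
  }, 1, "C3", 300)
  f <- seq(14, 26, by = 1)
  tf1 <- morlet_power(sine(1), freqs = f)
  tf2 <- morlet_power(sine(2), freqs = f)
  mid <- abs(tf1$time - 4) < 1
  prof <- rowMeans(tf1$power[1, , mid])
  expect_equal(f[which.max(prof)], 20)
  ratio <- mean(tf2$power[1, f == 20, mid]) / mean(tf1$power[1, f == 20, mid])
  expect_equal(ratio, 4, tolerance = 1e-6)
  expect_error(morlet_power(sine(1), freqs = f, n_cycles = 0.5), "n_cycles")
  expect_error(morlet_power(sine(1), freqs = c(20, 200)), "Nyquist")

  # linear chirp 15 -> 30 Hz over the epoch: the power ridge tracks the
  # instantaneous frequency mid-epoch within +/- 1 Hz
  chirp <- manual_epochs(function(t) {
    tt <- t - t[1]
    dur <- tt[length(tt)]
    matrix(sin(2 * pi * (15 * tt + 0.5 * (15 / dur) * tt^2)), 1, length(t))
  }, 1, "C3", 300)
  tfc <- morlet_power(chirp, freqs = seq(12, 33, by = 0.25))
  for (frac in c(0.4, 0.5, 0.6)) {
    ti <- which.min(abs(chirp$time - (chirp$time[1] + frac * 10)))
    f_inst <- 15 + 15 * frac
    f_hat <- tfc$freqs[which.max(tfc$power[1, , ti])]
    expect_lt(abs(f_hat - f_inst), 1)
  }
})

test_that("sampled-time fast path agrees with the full transform", {
  op <- oscillation_params(mrbd_depth = -0.4, pmbr_gain = 0.2)
  ep <- simulate_eeg_session(op, n_trials = 4, fs = 100,
                             epoch_window = c(-1, 7.5),
                             channels = c("C3", "CP3"), seed = 12)
  pts <- c(-0.5, 1.5, 6.5)
  full <- morlet_power(ep, freqs = c(15, 20, 25))
  fast <- morlet_power(ep, freqs = c(15, 20, 25), time_points = pts)
  idx <- vapply(pts, function(p) which.min(abs(full$time - p)), 1L)
  expect_equal(fast$power, full$power[, , idx, drop = FALSE],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("baseline rescaling: stationarity, closed form, and errors", {
  # flat-envelope sinusoid: percent change ~ 0 away from the epoch edges
  op <- sine_op(mrbd_depth = 0, pmbr_gain = 0)
  ep <- simulate_eeg_session(op, n_trials = 2, fs = 100,
                             epoch_window = c(-1, 7.5),
                             channels = c("C3", "C4"), seed = 15)
  tf <- morlet_power(ep, freqs = c(18, 20, 22))
  rel <- baseline_rescale(tf)
  interior <- rel$time > 0.5 & rel$time < 6.5
  expect_lt(max(abs(rowMeans(rel$power[, 2, interior]))), 5)
  expect_error(baseline_rescale(rel), "already rescaled")
  expect_error(baseline_rescale(tf, baseline = c(-30, -20)), "outside")

  # power halved in a window -> -50% there (sinusoid, amplitude 1/sqrt(2))
  s <- sqrt(0.5)
  op2 <- sine_op(mrbd_depth = s - 1)
  ep2 <- simulate_eeg_session(op2, 1, fs = 300, channels = "C3", seed = 16)
  tf2 <- morlet_power(ep2, freqs = 20)
  rel2 <- baseline_rescale(tf2)
  got <- mean(rel2$power[1, 1, rel2$time >= 1 & rel2$time <= 2])
  expect_equal(got, -50, tolerance = 0.01)
  # mrbd_depth = -0.3 in amplitude -> R = -51% (power factor 0.49)
  op3 <- sine_op(mrbd_depth = -0.3)
  ep3 <- simulate_eeg_session(op3, 1, fs = 300, channels = "C3", seed = 17)
  rel3 <- baseline_rescale(morlet_power(ep3, freqs = 20))
  got3 <- mean(rel3$power[1, 1, rel3$time >= 1 & rel3$time <= 2])
  expect_equal(got3, -51, tolerance = 0.01)
})

test_that("wavelet power of white noise scales linearly with variance", {
  pw <- vapply(c(1, 2, 4), function(v) {
    set.seed(20)
    ep <- manual_epochs(function(t) {
      matrix(rnorm(length(t), sd = sqrt(v)), 1, length(t))
    }, 8, "C3", 300)
    tf <- morlet_power(ep, freqs = c(15, 25, 35))
    mean(tf$power)
  }, numeric(1))
  expect_equal(pw[2] / pw[1], 2, tolerance = 0.05)
  expect_equal(pw[3] / pw[1], 4, tolerance = 0.05)
})

test_that("percent-change maps are invariant to signal scale", {
  op <- oscillation_params(mrbd_depth = -0.4, pmbr_gain = 0.2)
  ep <- simulate_eeg_session(op, n_trials = 10, fs = 100,
                             epoch_window = c(-1, 7.5),
                             channels = pool_channels_test(), seed = 21)
  bm1 <- session_beta_measures(ep)
  ep10 <- ep
  ep10$data <- ep$data * 10
  bm10 <- session_beta_measures(ep10)
  expect_lt(max(abs(bm1$mrbd - bm10$mrbd)), 1e-9)
  expect_lt(max(abs(bm1$pmbr - bm10$pmbr)), 1e-9)
  expect_equal(bm10$baseline_beta / bm1$baseline_beta, rep(100, 2))
})

test_that("injected envelope effects are recovered as band-average measures", {
  # default band source + 1/f noise, 100 trials: MRBD within 5 points;
  # PMBR is averaged over the two hemispheres (same injected truth) since
  # each hemisphere estimate carries the full source-power fluctuation
  op <- oscillation_params(mrbd_depth = -0.5, pmbr_gain = 0)
  ep <- simulate_eeg_session(op, n_trials = 100, fs = 300,
                             channels = pool_channels_test(), seed = 23)
  bm <- session_beta_measures(ep, freqs = coarse_freqs())
  expect_lt(max(abs(bm$mrbd - (-75))), 5)
  expect_lt(abs(mean(bm$pmbr)), 5)

  # pmbr_gain = 0.2 at 20 Hz: closed form +44% at the carrier frequency
  # (noiseless), and within estimator precision for the noisy band source
  opc <- sine_op(pmbr_gain = 0.2)
  epc <- simulate_eeg_session(opc, n_trials = 1, fs = 300,
                              channels = "C3", seed = 24)
  relc <- baseline_rescale(morlet_power(epc, freqs = 20))
  got <- mean(relc$power[1, 1, relc$time >= 6 & relc$time <= 7])
  expect_equal(got, 44, tolerance = 0.01)

  op2 <- oscillation_params(mrbd_depth = 0, pmbr_gain = 0.2)
  ep2 <- simulate_eeg_session(op2, n_trials = 100, fs = 300,
                              channels = pool_channels_test(), seed = 24)
  bm2 <- session_beta_measures(ep2, freqs = coarse_freqs())
  expect_lt(abs(mean(bm2$pmbr) - 44), 8)
})

test_that("hemisphere labels mirror exactly with the trained hand", {
  op <- oscillation_params(mrbd_depth = -0.3, pmbr_gain = 0.2)
  pars <- list(left = op, right = op)
  pars$right$mrbd_depth <- -0.6
  ep <- simulate_eeg_session(pars, n_trials = 6, fs = 100,
                             epoch_window = c(-1, 7.5),
                             channels = pool_channels_test(), seed = 25)
  right_hand <- session_beta_measures(ep, trained_hand = "right")
  left_hand <- session_beta_measures(ep, trained_hand = "left")
  expect_equal(right_hand$mrbd[right_hand$hemisphere == "contralateral"],
               left_hand$mrbd[left_hand$hemisphere == "ipsilateral"])
  expect_equal(right_hand$pmbr[right_hand$hemisphere == "contralateral"],
               left_hand$pmbr[left_hand$hemisphere == "ipsilateral"])
})

test_that("measured MRBD is monotone in the injected depth", {
  est <- vapply(c(0, -0.2, -0.4, -0.6), function(d) {
    op <- oscillation_params(mrbd_depth = d, pmbr_gain = 0.1)
    ep <- simulate_eeg_session(op, n_trials = 50, fs = 100,
                               epoch_window = c(-1, 7.5),
                               channels = pool_channels_test(),
                               seed = 30 + round(100 * abs(d)))
    mean(session_beta_measures(ep)$mrbd)
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})

test_that("window arguments outside the epoch raise errors", {
  op <- oscillation_params()
  ep <- simulate_eeg_session(op, 2, fs = 100, epoch_window = c(-1, 7.5),
                             channels = pool_channels_test(), seed = 31)
  tf <- morlet_power(ep, freqs = c(15, 20))
  rel <- baseline_rescale(tf)
  expect_error(extract_beta_measures(tf, rel, pmbr_window = c(8, 9)),
               "outside the epoch")
  expect_error(extract_beta_measures(tf, rel, mrbd_band = c(31, 40)),
               "not covered")
  expect_error(extract_beta_measures(rel, rel), "absolute")
  expect_error(extract_beta_measures(tf, tf), "rescaled")
})
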