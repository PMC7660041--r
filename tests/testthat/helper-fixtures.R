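# Shared fixtures, all generated in code.

quiet_bp <- function(...) {
  behavior_params(noise_sd = 0, fatigue_slope = 0, offline_boost = 0,
                  overnight_forgetting = 0, ...)
}

# Small sinusoid-mode oscillation parameters for closed-form checks.
sine_op <- function(mrbd_depth = -0.5, pmbr_gain = 0, noise_sd = 0, ...) {
  oscillation_params(beta_bw = 0, noise_sd = noise_sd,
                     mrbd_depth = mrbd_depth, pmbr_gain = pmbr_gain, ...)
}

# Fast small cohort for pipeline-level tests.
tiny_cohort_spec <- function(seed = 11, ...) {
  cohort_spec(n_patients = 8, n_controls = 0, seed = seed, n_trials = 8,
              eeg_fs = 80, epoch_window = c(-1, 7.5),
              channels = pool_channels_test(), ...)
}

pool_channels_test <- function() {
  c("C3", "C4", "C1", "C2", "CP1", "CP2", "CP3", "CP4")
}

# Independent OLS oracle: closed-form simple linear regression evaluated at x0.
ols_at <- function(x, y, x0) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  a + b * x0
}

# Deterministic epoch_set wrapper around an explicit signal builder:
# fun(t) must return a channels x samples matrix for one trial.
manual_epochs <- function(fun, n_trials, channels, fs, window = c(-1, 9)) {
  n <- round(diff(window) * fs)
  t <- window[1] + (seq_len(n) - 1) / fs
  data <- array(0, dim = c(n_trials, length(channels), n),
                dimnames = list(NULL, channels, NULL))
  for (tr in seq_len(n_trials)) data[tr, , ] <- fun(t)
  structure(list(data = data, channels = channels, fs = fs, time = t,
                 retained = seq_len(n_trials)),
            class = "epoch_set")
}
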