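# Raised-cosine box: 0 outside [a, b], 1 in the flat interior, cosine ramps
# of length `ramp` just inside the edges.
smooth_box <- function(t, a, b, ramp) {
  y <- numeric(length(t))
  y[t >= a + ramp & t <= b - ramp] <- 1
  up <- t > a & t < a + ramp
  y[up] <- 0.5 * (1 - cos(pi * (t[up] - a) / ramp))
  down <- t > b - ramp & t < b
  y[down] <- 0.5 * (1 - cos(pi * (b - t[down]) / ramp))
  y
}

# Amplitude envelope of one hemisphere's beta source.
beta_envelope <- function(t, pars) {
  1 + pars$mrbd_depth * smooth_box(t, pars$movement_window[1],
                                   pars$movement_window[2], pars$ramp) +
    pars$pmbr_gain * smooth_box(t, pars$rebound_window[1],
                                pars$rebound_window[2], pars$ramp)
}

# Spectrally shaped (1/f^exponent) Gaussian noise, one column per series,
# each column scaled to RMS `rms`.
pink_noise <- function(n, n_series, fs, exponent, rms) {
  white <- matrix(rnorm(n * n_series), n, n_series)
  if (exponent == 0) {
    return(white * rep(rms / sqrt(colMeans(white^2)), each = n))
  }
  spec <- mvfft(white)
  f <- c(1, seq_len(n - 1))            # guard DC
  f <- pmin(f, n - f)                  # two-sided frequency index
  shape <- (f * fs / n)^(-exponent / 2)
  shape[1] <- 0
  x <- Re(mvfft(spec * shape, inverse = TRUE)) / n
  x * rep(rms / sqrt(colMeans(x^2)), each = n)
}

# Stationary beta source realizations, one column per trial, each
# RMS-normalized to `amp`.
beta_source <- function(n, n_trials, fs, pars) {
  if (pars$beta_bw == 0) {
    ph <- runif(n_trials, 0, 2 * pi)
    t <- (seq_len(n) - 1) / fs
    return(pars$baseline_amp * sqrt(2) *
             sin(outer(2 * pi * pars$beta_freq * t, ph, `+`)))
  }
  lo <- pars$beta_freq - pars$beta_bw / 2
  hi <- pars$beta_freq + pars$beta_bw / 2
  spec <- mvfft(matrix(rnorm(n * n_trials), n, n_trials))
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  spec[f < lo | f > hi, ] <- 0
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  x * rep(pars$baseline_amp / sqrt(colMeans(x^2)), each = n)
}

#' Simulate one session of cue-aligned EEG epochs
#'
#' Each trial is 1/f background noise plus, per hemisphere, a sensorimotor
#' beta source with a piecewise-smooth amplitude envelope: baseline
#' amplitude before the cue, scaled by `(1 + mrbd_depth)` during the
#' movement window and by `(1 + pmbr_gain)` in the post-movement rebound
#' window, with raised-cosine transitions. Sources are mixed into channels
#' by the sensorimotor topography.
#'
#' @param params An [oscillation_params()] object applied to both
#'   hemispheres, or a list with elements `left` and `right`.
#' @param n_trials Number of trials (paper task: 120).
#' @param fs Sampling rate, Hz (default 300).
#' @param epoch_window Epoch window in seconds relative to the cue,
#'   default `c(-1, 9)`.
#' @param channels Channel labels; default [montage_64()].
#' @param seed Optional seed.
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array, microvolts), `channels`, `fs`, `time`, `retained`, and
#'   `ground_truth` (per-hemisphere envelopes and parameters).
#' @export
simulate_eeg_session <- function(params, n_trials, fs = 300,
                                 epoch_window = c(-1, 9),
                                 channels = montage_64(),
                                 seed = NULL) {
  if (inherits(params, "oscillation_params")) {
    params <- list(left = params, right = params)
  }
  stopifnot(all(c("left", "right") %in% names(params)))
  check_count(n_trials, "n_trials", lower = 1L)
  for (h in c("left", "right")) {
    top_f <- params[[h]]$beta_freq + params[[h]]$beta_bw / 2
    if (fs / 2 <= top_f) {
      stop_param("sampling rate ", fs, " Hz is too low for a beta source ",
                 "reaching ", top_f, " Hz (Nyquist)")
    }
  }
  with_seed(seed, {
    n <- round(diff(epoch_window) * fs)
    t <- epoch_window[1] + (seq_len(n) - 1) / fs
    n_chan <- length(channels)
    env <- list(); W <- list()
    for (h in c("left", "right")) {
      env[[h]] <- beta_envelope(t, params[[h]])
      topo <- params[[h]]$topography
      if (is.null(topo)) topo <- source_topography(h)
      w <- setNames(numeric(n_chan), channels)
      keep <- intersect(names(topo), channels)
      w[keep] <- topo[keep]
      W[[h]] <- w
    }
    # sources: n x trials per hemisphere; mix into an n x (trials*channels)
    # matrix, then add channel noise and reshape
    src <- lapply(c(left = "left", right = "right"), function(h) {
      beta_source(n, n_trials, fs, params[[h]]) * env[[h]]
    })
    flat <- matrix(0, n, n_trials * n_chan)
    for (h in c("left", "right")) {
      w <- W[[h]]
      nz <- which(w != 0)
      for (ci in nz) {
        cols <- (ci - 1L) * n_trials + seq_len(n_trials)
        flat[, cols] <- flat[, cols] + src[[h]] * w[ci]
      }
    }
    nsd <- max(params$left$noise_sd, params$right$noise_sd)
    if (nsd > 0) {
      flat <- flat + pink_noise(n, n_trials * n_chan, fs,
                                params$left$background_exponent, nsd)
    }
    data <- aperm(array(flat, dim = c(n, n_trials, n_chan)), c(2, 3, 1))
    dimnames(data) <- list(NULL, channels, NULL)
    structure(list(data = data, channels = channels, fs = fs, time = t,
                   retained = seq_len(n_trials),
                   ground_truth = list(envelope = env, weights = W,
                                       params = params)),
              class = "epoch_set")
  })
}
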