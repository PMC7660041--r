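#' Construct a continuous EEG recording
#'
#' @param signal Channels x samples numeric matrix, microvolts.
#' @param channels Channel labels (10-10 names), unique, one per row.
#' @param fs Sampling rate, Hz.
#' @param events Tibble/data.frame with columns `onset_sample` (strictly
#'   increasing, within the record) and `condition` (`"flexion"` /
#'   `"extension"`).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(signal, channels, fs, events) {
  if (!is.matrix(signal) || nrow(signal) != length(channels)) {
    stop_param("`signal` must be a channels x samples matrix matching `channels`")
  }
  if (anyDuplicated(channels)) stop_param("channel labels must be unique")
  events <- tibble::as_tibble(events)
  if (!all(c("onset_sample", "condition") %in% names(events))) {
    stop_param("`events` needs columns onset_sample and condition")
  }
  if (nrow(events) && (any(diff(events$onset_sample) <= 0))) {
    stop_param("event onsets must be strictly increasing")
  }
  if (nrow(events) && (min(events$onset_sample) < 1 ||
                       max(events$onset_sample) > ncol(signal))) {
    stop_param("event onsets fall outside the recording")
  }
  structure(list(signal = signal, channels = channels, fs = fs,
                 events = events),
            class = "eeg_recording")
}

# Second-order IIR notch (biquad), centre `f0`, quality factor `Q`.
notch_coef <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Preprocess a continuous EEG recording
#'
#' Average-references the signal, applies a zero-phase 4th-order Butterworth
#' band-pass (5-100 Hz) and a zero-phase 50 Hz notch (second-order IIR,
#' Q = 30), and resamples to 300 Hz, remapping event onsets to the new rate.
#'
#' @param rec An `eeg_recording` with sampling rate > 200 Hz.
#' @param band Band-pass edges, Hz.
#' @param notch Notch centre frequency, Hz (`NULL` disables).
#' @param notch_q Notch quality factor.
#' @param target_fs Output sampling rate, Hz.
#' @param pools Optional [electrode_pools()]; the recording must contain
#'   every pooled channel or an error lists the absentees.
#' @return A preprocessed `eeg_recording` at `target_fs`.
#' @export
preprocess <- function(rec, band = c(5, 100), notch = 50, notch_q = 30,
                       target_fs = 300, pools = NULL) {
  if (rec$fs <= 200) stop_param("preprocessing expects a sampling rate > 200 Hz")
  if (!is.null(pools)) {
    absent <- setdiff(pool_channels(pools), rec$channels)
    if (length(absent)) {
      stop_param("recording is missing pooled channels: ",
                 paste(absent, collapse = ", "))
    }
  }
  x <- rec$signal
  x <- sweep(x, 2, colMeans(x))                  # average reference
  bp <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  for (i in seq_len(nrow(x))) {
    x[i, ] <- signal::filtfilt(bp, x[i, ])
  }
  if (!is.null(notch)) {
    nc <- notch_coef(notch, rec$fs, notch_q)
    flt <- signal::Arma(b = nc$b, a = nc$a)
    for (i in seq_len(nrow(x))) {
      x[i, ] <- signal::filtfilt(flt, x[i, ])
    }
  }
  events <- rec$events
  if (target_fs != rec$fs) {
    g <- gcd_int(round(target_fs), round(rec$fs))
    p <- round(target_fs) / g
    q <- round(rec$fs) / g
    new <- t(apply(x, 1, function(ch) signal::resample(ch, p, q)))
    events$onset_sample <- pmax(1L, pmin(ncol(new),
      as.integer(round((events$onset_sample - 1) * target_fs / rec$fs) + 1L)))
    x <- new
  }
  eeg_recording(x, rec$channels, target_fs, events)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Cut cue-aligned epochs and reject artifact trials
#'
#' Epochs the recording around each event and drops trials whose
#' peak-to-peak amplitude on any monitored channel exceeds `threshold`
#' (microvolts), emulating exclusion of artifact-contaminated trials.
#'
#' @param rec An `eeg_recording`.
#' @param window Epoch window, seconds relative to the cue (default -1..9).
#' @param threshold Peak-to-peak rejection threshold, microvolts
#'   (default 150; `Inf` retains everything).
#' @param channels Channels monitored for rejection; default all.
#' @return An `epoch_set` with `retained` holding the surviving trial
#'   indices.
#' @export
epoch_and_reject <- function(rec, window = c(-1, 9), threshold = 150,
                             channels = NULL) {
  fs <- rec$fs
  n_epoch <- round(diff(window) * fs)
  offset <- round(window[1] * fs)
  n_rec <- ncol(rec$signal)
  onsets <- rec$events$onset_sample
  if (!length(onsets)) stop_param("recording has no events to epoch")
  first <- onsets + offset
  last <- first + n_epoch - 1L
  if (any(first < 1L) || any(last > n_rec)) {
    bad <- which(first < 1L | last > n_rec)
    stop_param("epoch window does not fit inside the record for event(s) ",
               paste(bad, collapse = ", "))
  }
  if (is.null(channels)) channels <- rec$channels
  ch_idx <- match(channels, rec$channels)
  if (anyNA(ch_idx)) {
    stop_param("rejection channels absent from recording: ",
               paste(channels[is.na(ch_idx)], collapse = ", "))
  }
  n_trials <- length(onsets)
  data <- array(0, dim = c(n_trials, nrow(rec$signal), n_epoch),
                dimnames = list(NULL, rec$channels, NULL))
  for (tr in seq_len(n_trials)) {
    data[tr, , ] <- rec$signal[, first[tr]:last[tr]]
  }
  ptp <- apply(data[, ch_idx, , drop = FALSE], 1, function(m) {
    max(apply(m, 1, function(ch) diff(range(ch))))
  })
  keep <- which(ptp <= threshold)
  if (!length(keep)) stop_param("all trials rejected at threshold ", threshold)
  structure(list(data = data[keep, , , drop = FALSE], channels = rec$channels,
                 fs = fs, time = window[1] + (seq_len(n_epoch) - 1) / fs,
                 retained = keep),
            class = "epoch_set")
}
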