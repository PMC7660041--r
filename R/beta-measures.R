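mean_window <- function(tf, chans, band, window) {
  ch_idx <- match(chans, tf$channels)
  if (anyNA(ch_idx)) {
    stop_param("pooled channels absent from time-frequency object: ",
               paste(chans[is.na(ch_idx)], collapse = ", "))
  }
  f_sel <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  t_sel <- which(tf$time >= window[1] & tf$time <= window[2])
  if (!length(f_sel)) stop_param("frequency band [", band[1], ", ", band[2],
                                 "] not covered by the analysis grid")
  if (!length(t_sel)) stop_param("time window [", window[1], ", ", window[2],
                                 "] lies outside the epoch")
  mean(tf$power[ch_idx, f_sel, t_sel])
}

#' Extract beta measures per hemisphere
#'
#' Computes, per hemisphere, the three beta parameters: absolute
#' pre-movement (resting) beta power, movement-related beta
#' desynchronization (MRBD, percent; expected <= 0) and post-movement beta
#' rebound (PMBR, percent; expected >= 0). MRBD is the mean percent change
#' over 1-2 s x 15-30 Hz in the MRBD electrode pool; PMBR the mean over
#' 6-7 s x 10-25 Hz in the PMBR pool; resting power the mean absolute power
#' over the baseline window x 15-30 Hz in the resting pool. Hemispheres are
#' labelled contralateral/ipsilateral to the trained hand.
#'
#' @param tf_abs `tf_power` with absolute power.
#' @param tf_rel `tf_power` rescaled to percent change ([baseline_rescale()]).
#' @param pools An [electrode_pools()] object.
#' @param trained_hand `"right"` or `"left"` (the generator's mirror flag).
#' @param mrbd_window,mrbd_band,pmbr_window,pmbr_band,rest_window,rest_band
#'   Analysis windows (seconds) and bands (Hz).
#' @param subject,session Labels carried into the output.
#' @return Tibble with one row per hemisphere: subject, session, hemisphere,
#'   baseline_beta, mrbd, pmbr.
#' @export
extract_beta_measures <- function(tf_abs, tf_rel, pools = electrode_pools(),
                                  trained_hand = "right",
                                  mrbd_window = c(1, 2), mrbd_band = c(15, 30),
                                  pmbr_window = c(6, 7), pmbr_band = c(10, 25),
                                  rest_window = c(-0.9, 0), rest_band = c(15, 30),
                                  subject = NA_character_,
                                  session = NA_character_) {
  if (!isTRUE(tf_rel$rescaled)) {
    stop_param("`tf_rel` must be baseline-rescaled percent change")
  }
  if (isTRUE(tf_abs$rescaled)) {
    stop_param("`tf_abs` must hold absolute power")
  }
  hmap <- hemisphere_map(trained_hand)
  rows <- lapply(names(hmap), function(hemi) {
    side <- hmap[[hemi]]
    tibble::tibble(
      subject = subject, session = session, hemisphere = hemi,
      baseline_beta = mean_window(tf_abs, pools$rest[[side]], rest_band, rest_window),
      mrbd = mean_window(tf_rel, pools$mrbd[[side]], mrbd_band, mrbd_window),
      pmbr = mean_window(tf_rel, pools$pmbr[[side]], pmbr_band, pmbr_window))
  })
  dplyr::bind_rows(rows)
}

#' Beta measures for one epoch set in a single call
#'
#' Convenience wrapper: Morlet transform restricted to the pooled channels,
#' baseline rescaling, and [extract_beta_measures()]. With
#' `time_points` (default: a 0.1 s raster over the three analysis windows)
#' the transform is evaluated only where the measures need it, which is the
#' fast path for simulation studies.
#'
#' @param epochs An `epoch_set`.
#' @param pools An [electrode_pools()] object.
#' @param trained_hand `"right"` or `"left"`.
#' @param freqs Analysis frequencies, Hz.
#' @param baseline Baseline window for rescaling, seconds.
#' @param time_points Epoch times at which to evaluate power, or `NULL` for
#'   the full time axis.
#' @param ... Passed to [extract_beta_measures()].
#' @return Tibble as for [extract_beta_measures()].
#' @export
session_beta_measures <- function(epochs, pools = electrode_pools(),
                                  trained_hand = "right",
                                  freqs = measure_freqs(),
                                  baseline = c(-0.9, 0),
                                  time_points = beta_time_points(),
                                  ...) {
  keep <- intersect(epochs$channels, pool_channels(pools))
  sub <- epochs
  sub$data <- epochs$data[, keep, , drop = FALSE]
  sub$channels <- keep
  tf_abs <- morlet_power(sub, freqs = freqs, time_points = time_points)
  tf_rel <- baseline_rescale(tf_abs, baseline = baseline)
  extract_beta_measures(tf_abs, tf_rel, pools = pools,
                        trained_hand = trained_hand, ...)
}

#' @rdname session_beta_measures
#' @param step Raster step within the analysis windows, seconds.
#' @export
beta_time_points <- function(step = 0.1) {
  c(seq(-0.9, -0.05, by = step), seq(1, 2, by = step), seq(6, 7, by = step))
}
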