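# Complex Morlet kernel at frequency f: unit-energy Gaussian-windowed
# exponential with temporal width sigma_t = n_cycles / (2 pi f), truncated
# at +/- trunc_sd sigma_t.
morlet_kernel <- function(f, fs, n_cycles = 7, trunc_sd = 4) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- floor(trunc_sd * sigma_t * fs)
  tau <- (-half:half) / fs
  k <- exp(2i * pi * f * tau) * exp(-tau^2 / (2 * sigma_t^2))
  k / sqrt(sum(Mod(k)^2) / fs)
}

# Mirror-pad a samples x series matrix by n_pad rows on each side, using
# point-symmetric (odd) reflection about the end samples: continuous in
# value and first derivative, so the pad boundary sheds far less broadband
# splatter into near-edge power estimates than a plain mirror.
mirror_pad <- function(m, n_pad) {
  n <- nrow(m)
  n_pad <- min(n_pad, n - 1L)
  top <- 2 * rep(m[1, ], each = n_pad) - m[(n_pad + 1):2, , drop = FALSE]
  bottom <- 2 * rep(m[n, ], each = n_pad) - m[(n - 1):(n - n_pad), , drop = FALSE]
  rbind(top, m, bottom)
}

#' Morlet wavelet time-frequency power
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (default 7 cycles, so temporal width \eqn{\sigma_t = 7/(2\pi f)}),
#' squares the magnitude, and averages across trials. Epochs are
#' mirror-padded by `pad` seconds before convolution and cropped after, to
#' control edge effects near the baseline window.
#'
#' With `time_points` set, coefficients are computed only at the requested
#' epoch times (truncated-kernel inner products); power estimates at those
#' instants are identical to the full transform up to the shared kernel
#' truncation. This is the fast path for window-averaged beta measures in
#' large simulation studies.
#'
#' @param epochs An `epoch_set`.
#' @param freqs Analysis frequencies, Hz. Default 5-45 Hz in 0.1 Hz steps;
#'   see [coarse_freqs()] for the 0.5 Hz test grid.
#' @param n_cycles Wavelet cycles (>= 1).
#' @param pad Mirror-padding length, seconds.
#' @param time_points Optional epoch times (seconds) at which to evaluate.
#' @param trunc_sd Kernel truncation, in units of sigma_t.
#' @param chunk_channels Channels processed per FFT batch (memory control).
#' @return A `tf_power` object: `power` (channels x freqs x times array,
#'   trial-averaged), `freqs`, `time`, `fs`, `channels`,
#'   `rescaled = FALSE`.
#' @export
morlet_power <- function(epochs, freqs = seq(5, 45, by = 0.1), n_cycles = 7,
                         pad = 1, time_points = NULL, trunc_sd = 4,
                         chunk_channels = 8L) {
  if (n_cycles < 1) stop_param("`n_cycles` must be >= 1")
  fs <- epochs$fs
  if (max(freqs) >= fs / 2) {
    stop_param("maximum analysis frequency ", max(freqs),
               " Hz is not below Nyquist (", fs / 2, " Hz)")
  }
  dims <- dim(epochs$data)
  n_trials <- dims[1]; n_chan <- dims[2]; n <- dims[3]
  kernels <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = n_cycles,
                    trunc_sd = trunc_sd)
  n_pad <- min(round(pad * fs), n - 1L)

  if (!is.null(time_points)) {
    return(morlet_power_at(epochs, freqs, kernels, time_points, n_pad))
  }

  max_len <- max(lengths(kernels))
  nfft <- nextn(n + 2 * n_pad + max_len, 2)
  kvecs <- lapply(kernels, function(k) {
    half <- (length(k) - 1) / 2
    kv <- complex(nfft)
    kv[1:(half + 1)] <- k[(half + 1):length(k)]
    kv[(nfft - half + 1):nfft] <- k[1:half]
    fft(kv)
  })
  out <- array(0, dim = c(n_chan, length(freqs), n),
               dimnames = list(epochs$channels, NULL, NULL))
  for (ch0 in seq(1L, n_chan, by = chunk_channels)) {
    chans <- ch0:min(ch0 + chunk_channels - 1L, n_chan)
    # samples x (trial within channel) matrix
    m <- matrix(aperm(epochs$data[, chans, , drop = FALSE], c(3, 1, 2)),
                nrow = n)
    m <- mirror_pad(m, n_pad)
    m <- rbind(m, matrix(0, nfft - nrow(m), ncol(m)))
    spec <- mvfft(m)
    for (fi in seq_along(freqs)) {
      co <- mvfft(spec * kvecs[[fi]], inverse = TRUE) / nfft
      pw <- Mod(co[n_pad + seq_len(n), , drop = FALSE])^2
      dim(pw) <- c(n, n_trials, length(chans))
      out[chans, fi, ] <- t(colMeans(aperm(pw, c(2, 1, 3))))
    }
  }
  structure(list(power = out, freqs = freqs, time = epochs$time, fs = fs,
                 channels = epochs$channels, rescaled = FALSE),
            class = "tf_power")
}

# Sparse-kernel evaluation of the wavelet transform at selected times.
morlet_power_at <- function(epochs, freqs, kernels, time_points, n_pad) {
  fs <- epochs$fs
  dims <- dim(epochs$data)
  n_trials <- dims[1]; n_chan <- dims[2]; n <- dims[3]
  idx <- round((time_points - epochs$time[1]) * fs) + 1L
  if (any(idx < 1L) || any(idx > n)) {
    stop_param("`time_points` outside the epoch window")
  }
  m <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
  m <- mirror_pad(m, n_pad)
  np <- nrow(m)
  out <- array(0, dim = c(n_chan, length(freqs), length(idx)),
               dimnames = list(epochs$channels, NULL, NULL))
  for (fi in seq_along(freqs)) {
    k <- kernels[[fi]]
    half <- (length(k) - 1) / 2
    if (half > n_pad) stop_param("kernel exceeds mirror padding; increase `pad`")
    cols <- rep(idx + n_pad, each = length(k)) +
      rep(-half:half, times = length(idx))
    rows <- rep(seq_along(idx), each = length(k))
    Sr <- Matrix::sparseMatrix(i = rows, j = cols, x = rep(Re(k), length(idx)),
                               dims = c(length(idx), np))
    Si <- Matrix::sparseMatrix(i = rows, j = cols, x = rep(Im(k), length(idx)),
                               dims = c(length(idx), np))
    pw <- as.matrix(Sr %*% m)^2 + as.matrix(Si %*% m)^2
    dim(pw) <- c(length(idx), n_trials, n_chan)
    out[, fi, ] <- t(colMeans(aperm(pw, c(2, 1, 3))))
  }
  structure(list(power = out, freqs = freqs, time = time_points, fs = fs,
                 channels = epochs$channels, rescaled = FALSE),
            class = "tf_power")
}

#' Coarse analysis-frequency grids
#'
#' `coarse_freqs()` is the 0.5 Hz step grid over 5-45 Hz used for fast test
#' runs; `measure_freqs()` restricts to the 10-30 Hz range that the beta
#' measures integrate over, at a configurable step, for large simulation
#' studies.
#'
#' @param step Frequency step, Hz.
#' @return Numeric vector of frequencies.
#' @export
coarse_freqs <- function(step = 0.5) seq(5, 45, by = step)

#' @rdname coarse_freqs
#' @export
measure_freqs <- function(step = 2.5) seq(10, 30, by = step)

#' Rescale time-frequency power to percent change from baseline
#'
#' \eqn{R(c,f,t) = 100 (P(c,f,t) - B(c,f)) / B(c,f)} where \eqn{B} is the
#' time-mean of power over the baseline window. The default baseline is
#' -0.9 to 0 s: the pre-movement second minus the 0.1 s abutting the epoch
#' edge.
#'
#' @param tf A `tf_power` object with absolute power.
#' @param baseline Baseline window, seconds.
#' @return A `tf_power` object with `rescaled = TRUE`, percent units.
#' @export
baseline_rescale <- function(tf, baseline = c(-0.9, 0)) {
  if (isTRUE(tf$rescaled)) stop_param("time-frequency object is already rescaled")
  sel <- tf$time >= baseline[1] & tf$time <= baseline[2]
  if (!any(sel)) stop_param("baseline window lies outside the epoch")
  B <- apply(tf$power[, , sel, drop = FALSE], c(1, 2), mean)
  if (any(B <= 0)) stop_param("baseline power is zero for some channel/frequency")
  R <- 100 * (tf$power - as.vector(B)) / as.vector(B)
  out <- tf
  out$power <- R
  out$rescaled <- TRUE
  out$baseline <- baseline
  out
}
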