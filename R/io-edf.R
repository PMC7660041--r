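# Minimal European Data Format (EDF) support: 16-bit samples, 1-second data
# records, one signal per EEG channel. Covers what the pipeline writes and
# reads back; not a general-purpose EDF implementation.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

# numeric as the widest string that fits a signed 8-char EDF header field
edf_num <- function(v) {
  for (d in 7:3) {
    s <- trimws(formatC(v, format = "g", digits = d))
    if (nchar(s) <= 7) return(s)
  }
  s
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records; the recording is truncated to
#' whole records. Events are written alongside as a tab-separated table
#' `<path>.events.tsv` with columns `onset_sample` and `condition`.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- round(rec$fs)
  if (fs != rec$fs) stop_param("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$signal)
  n_rec <- floor(ncol(rec$signal) / fs)
  if (n_rec < 1) stop_param("recording shorter than one EDF data record")
  x <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]
  pmax_ <- pmax(apply(abs(x), 1, max), 1e-6)
  # store the physical range exactly as it prints in the 8-char header
  # field (sign included), so the gain used for writing matches the one
  # read back; round the range up so no sample clips
  pmax_ <- vapply(pmax_, function(v) {
    for (mult in c(1, 1.0005, 1.005, 1.05)) {
      s <- edf_num(v * mult)
      p <- as.numeric(s)
      if (p >= v) return(p)
    }
    v
  }, numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("synthetic subject", 80),
    edf_field("betalearn recording", 80),
    edf_field("01.01.20", 8), edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(1, 8), edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_field, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  per_sig(rec$channels, 16)
  per_sig(rep("", ns), 80)
  per_sig(rep("uV", ns), 8)
  per_sig(paste0("-", vapply(pmax_, edf_num, "")), 8)
  per_sig(vapply(pmax_, edf_num, ""), 8)
  per_sig(rep("-32767", ns), 8)
  per_sig(rep("32767", ns), 8)
  per_sig(rep("", ns), 80)
  per_sig(rep(fs, ns), 8)
  per_sig(rep("", ns), 32)
  scale <- 32767 / pmax_
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- round(x[, cols, drop = FALSE] * scale)
    block <- pmax(pmin(block, 32767), -32767)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  ev_path <- paste0(path, ".events.tsv")
  utils::write.table(rec$events, ev_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1) stop_param("mixed sampling rates are not supported")
  fs <- spr[1] / dur
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    sig[, cols] <- t(block)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- sig * gain + (pmin_ - dmin * gain)
  list(signal = sig, channels = labels, fs = fs)
}

#' Read an EEG recording (EDF plus events table)
#'
#' Reads `<path>` as EDF and the sibling `<path>.events.tsv` events table,
#' validating channel labels and event onsets.
#'
#' @param path Path to the `.edf` file.
#' @return An `eeg_recording`.
#' @export
read_eeg <- function(path) {
  if (!file.exists(path)) stop_param("EDF file not found: ", path)
  ev_path <- paste0(path, ".events.tsv")
  if (!file.exists(ev_path)) {
    stop_param("events table not found alongside recording: ", ev_path)
  }
  raw <- read_edf(path)
  events <- tibble::as_tibble(utils::read.delim(ev_path))
  eeg_recording(raw$signal, raw$channels, raw$fs, events)
}
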