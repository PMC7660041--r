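SESSION_BLOCKS <- c(training = 40L, retest1 = 5L, retest2 = 10L)

#' Closed-form mean learning curve
#'
#' Expected block RMSE (degrees) as a function of cumulative block number.
#' General improvement follows a saturating exponential in cumulative
#' practice; the repeated sequence improves by an extra `sequence_gain`
#' fraction; fatigue accrues linearly after `fatigue_onset` during the
#' training session only. Retest sessions are shifted multiplicatively by
#' the offline boost (both sequences) and, in retest2, by overnight
#' forgetting (repeated sequence only).
#'
#' @param params A [behavior_params()] object.
#' @param blocks Cumulative block numbers (training 1-40, retest1 41-45,
#'   retest2 46-55).
#' @param sequence `"repeated"` or `"random"`.
#' @param session `"training"`, `"retest1"` or `"retest2"`.
#' @return Numeric vector of expected block RMSEs, degrees.
#' @export
learning_curve <- function(params, blocks, sequence = c("repeated", "random"),
                           session = c("training", "retest1", "retest2")) {
  sequence <- match.arg(sequence)
  session <- match.arg(session)
  amp <- params$learning_amplitude *
    (1 + if (sequence == "repeated") params$sequence_gain else 0)
  m <- params$initial_rmse - amp * (1 - exp(-params$learning_rate * blocks))
  if (session == "training") {
    m <- m + params$fatigue_slope * pmax(0, blocks - params$fatigue_onset)
  } else {
    m <- m * (1 - params$offline_boost)
    if (session == "retest2" && sequence == "repeated") {
      m <- m * (1 + params$overnight_forgetting)
    }
  }
  m
}

# Smooth target trajectory through `n_pos` waypoint angles.
target_trajectory <- function(waypoints, duration, fs) {
  n <- length(waypoints)
  knots <- seq(0, duration, length.out = n)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  spline(knots, waypoints, xout = t, method = "natural")$y
}

# Smooth tracking-error trace with RMS scaled exactly to `rms`.
error_trace <- function(n, rms, phi = 0.9) {
  if (rms <= 0) return(numeric(n))
  e <- as.numeric(stats::filter(rnorm(n + 50), phi, method = "recursive"))
  e <- e[-seq_len(50)]
  e * (rms / sqrt(mean(e^2)))
}

#' Simulate one tracking session
#'
#' Generates paired target/wrist angle traces for every block of a session.
#' Each block presents one repeated-sequence and one random-sequence
#' trajectory (12 waypoint positions along the movement arc). The wrist
#' trace is the target trace plus a smooth error process whose per-block RMS
#' equals the learning-curve mean perturbed by block-level noise, so that
#' with `noise_sd = 0` the block RMSE reproduces [learning_curve()] exactly.
#'
#' @param params A [behavior_params()] object.
#' @param n_blocks Number of blocks (>= 1).
#' @param session Session label (`"training"`, `"retest1"`, `"retest2"`).
#' @param block_offset Cumulative blocks of practice before this session
#'   (40 at retest1, 45 at retest2 under the standard design).
#' @param mean_shift Additive shift of this session's mean RMSE, degrees
#'   (used by the cohort generator to plant subject-level effects).
#' @param repeated_waypoints Waypoints of the repeated sequence; drawn once
#'   if `NULL`.
#' @param subject,seed Subject id carried into the blocks and optional seed.
#' @return List of `tracking_block` objects (fields `subject`, `session`,
#'   `block_index`, `sequence_type`, `target_deg`, `wrist_deg`, `fs`).
#' @export
simulate_tracking_session <- function(params, n_blocks,
                                      session = "training",
                                      block_offset = 0L,
                                      mean_shift = 0,
                                      repeated_waypoints = NULL,
                                      subject = "s01",
                                      seed = NULL) {
  check_count(n_blocks, "n_blocks", lower = 1L)
  with_seed(seed, {
    fs <- params$sample_rate
    n_samp <- round(params$block_duration * fs)
    if (is.null(repeated_waypoints)) {
      repeated_waypoints <- runif(12, -params$range_deg, params$range_deg)
    }
    blocks <- vector("list", 2L * n_blocks)
    k <- 0L
    for (b in seq_len(n_blocks)) {
      cum <- block_offset + b
      for (seqt in c("repeated", "random")) {
        wp <- if (seqt == "repeated") repeated_waypoints else {
          runif(12, -params$range_deg, params$range_deg)
        }
        target <- target_trajectory(wp, params$block_duration, fs)
        m <- learning_curve(params, cum, seqt, session) + mean_shift
        sigma <- m + if (params$noise_sd > 0) rnorm(1, 0, params$noise_sd) else 0
        sigma <- max(sigma, 0.05)
        wrist <- target + error_trace(n_samp, sigma)
        k <- k + 1L
        blocks[[k]] <- structure(
          list(subject = subject, session = session, block_index = b,
               sequence_type = seqt, target_deg = target, wrist_deg = wrist,
               fs = fs),
          class = "tracking_block")
      }
    }
    blocks
  })
}

#' Convert tracking blocks to a tidy sample table
#'
#' @param blocks List of `tracking_block` objects.
#' @return Tibble with columns subject, session, block, sequence_type,
#'   sample_index, target_deg, wrist_deg.
#' @export
tracking_to_table <- function(blocks) {
  dplyr::bind_rows(lapply(blocks, function(b) {
    tibble::tibble(subject = b$subject, session = b$session,
                   block = b$block_index, sequence_type = b$sequence_type,
                   sample_index = seq_along(b$target_deg),
                   target_deg = b$target_deg, wrist_deg = b$wrist_deg)
  }))
}

#' Reconstruct tracking blocks from a tidy sample table
#'
#' Inverse of [tracking_to_table()]; `fs` must be supplied because the tidy
#' schema stores sample indices, not times.
#'
#' @param tab Tibble in the [tracking_to_table()] schema.
#' @param fs Behavioural sampling rate, Hz.
#' @return List of `tracking_block` objects.
#' @export
table_to_tracking <- function(tab, fs) {
  keys <- unique(tab[c("subject", "session", "block", "sequence_type")])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    rows <- tab$subject == k$subject & tab$session == k$session &
      tab$block == k$block & tab$sequence_type == k$sequence_type
    sub <- tab[rows, ]
    sub <- sub[order(sub$sample_index), ]
    structure(list(subject = k$subject, session = k$session,
                   block_index = k$block, sequence_type = k$sequence_type,
                   target_deg = sub$target_deg, wrist_deg = sub$wrist_deg,
                   fs = fs),
              class = "tracking_block")
  })
}
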