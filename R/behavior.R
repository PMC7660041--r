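#' Block root-mean-square tracking error
#'
#' RMSE between the wrist and target angle traces of one tracking block,
#' \eqn{\sqrt{\mathrm{mean}((wrist_i - target_i)^2)}}; smaller values
#' reflect better motor performance.
#'
#' @param block A `tracking_block`, or anything with numeric elements
#'   `target_deg` and `wrist_deg` of equal length >= 2.
#' @return RMSE in degrees.
#' @export
compute_rmse <- function(block) {
  target <- block$target_deg
  wrist <- block$wrist_deg
  if (length(target) < 2L || length(target) != length(wrist)) {
    stop_param("tracking block needs target/wrist series of equal length >= 2")
  }
  if (anyNA(target) || anyNA(wrist)) stop_param("tracking block contains NA samples")
  sqrt(mean((wrist - target)^2))
}

#' Regression-corrected session endpoints
#'
#' Fits an ordinary least-squares line across the first five and the last
#' five blocks of a session's RMSE series and evaluates the fits at the
#' first and final block respectively, yielding performance estimates
#' corrected for temporary effects such as fatigue or boredom. For a
#' 5-block session both estimates come from the same fitted line.
#'
#' @param block_rmse Ordered numeric vector of block RMSEs for one session
#'   and sequence type (>= 5 blocks).
#' @param session Session label used in error messages.
#' @param eval_at Blocks at which the two fits are evaluated; default the
#'   first and final block.
#' @return Named numeric vector `c(start, end)`, degrees.
#' @export
corrected_endpoints <- function(block_rmse, session = "session",
                                eval_at = NULL) {
  n <- length(block_rmse)
  if (n < 5L) {
    stop_param("session '", session, "' has ", n,
               " blocks; at least 5 are required for endpoint correction")
  }
  if (anyNA(block_rmse)) stop_param("session '", session, "' has missing block RMSEs")
  if (is.null(eval_at)) eval_at <- c(1, n)
  first_idx <- 1:5
  last_idx <- (n - 4):n
  fit_first <- lm(y ~ x, data = data.frame(x = first_idx, y = block_rmse[first_idx]))
  fit_last <- lm(y ~ x, data = data.frame(x = last_idx, y = block_rmse[last_idx]))
  start <- unname(predict(fit_first, data.frame(x = eval_at[1])))
  end <- unname(predict(fit_last, data.frame(x = eval_at[2])))
  c(start = start, end = end)
}

#' Score a subject's tracking sessions into a performance timeline
#'
#' Computes per-block RMSE series for every session and sequence type and
#' derives the six corrected endpoint estimates: T0/T1 (start/end of
#' training), T2/T3 (retest1) and T4/T5 (retest2), separately per sequence
#' type.
#'
#' @param blocks List of `tracking_block` objects covering sessions
#'   `training`, `retest1` and `retest2` for one subject.
#' @return An object of class `performance_timeline`: list with `subject`,
#'   `rmse` (tibble session/sequence_type/block/rmse) and `endpoints`
#'   (tibble sequence_type x T0..T5).
#' @export
performance_timeline <- function(blocks) {
  stopifnot(length(blocks) > 0)
  subject <- blocks[[1]]$subject
  rmse <- tibble::tibble(
    subject = vapply(blocks, `[[`, "", "subject"),
    session = vapply(blocks, `[[`, "", "session"),
    block = vapply(blocks, `[[`, 0L, "block_index"),
    sequence_type = vapply(blocks, `[[`, "", "sequence_type"),
    rmse = vapply(blocks, compute_rmse, numeric(1)))
  endpoint_of <- c(training = "T0T1", retest1 = "T2T3", retest2 = "T4T5")
  eps <- list()
  for (seqt in unique(rmse$sequence_type)) {
    row <- list(sequence_type = seqt)
    for (sess in names(endpoint_of)) {
      sub <- rmse[rmse$session == sess & rmse$sequence_type == seqt, ]
      sub <- sub[order(sub$block), ]
      if (nrow(sub) == 0) stop_param("no blocks for session '", sess, "'")
      ep <- corrected_endpoints(sub$rmse, session = sess)
      labs <- substring(endpoint_of[[sess]], c(1, 3), c(2, 4))
      row[[labs[1]]] <- ep[["start"]]
      row[[labs[2]]] <- ep[["end"]]
    }
    eps[[seqt]] <- tibble::as_tibble(row)
  }
  structure(list(subject = subject, rmse = rmse,
                 endpoints = dplyr::bind_rows(eps)),
            class = "performance_timeline")
}

DELTA_PAIRS <- list(c("T0", "T1"), c("T1", "T2"), c("T3", "T4"),
                    c("T0", "T2"), c("T0", "T4"))

#' Performance change measures between endpoints
#'
#' Signed differences between corrected endpoints, with positive values
#' meaning improvement (RMSE decrease): delta = earlier - later. Percentage
#' deltas are expressed relative to the subject's repeated-sequence T0.
#'
#' @param timeline A [performance_timeline()] object.
#' @return Tibble with columns sequence_type, pair, delta_deg, delta_pct.
#' @export
delta_performance <- function(timeline) {
  eps <- timeline$endpoints
  need <- unique(unlist(DELTA_PAIRS))
  missing <- setdiff(need, names(eps))
  if (length(missing)) {
    stop_param("missing endpoints: ", paste(missing, collapse = ", "))
  }
  t0_rep <- eps$T0[eps$sequence_type == "repeated"]
  if (length(t0_rep) != 1 || !is.finite(t0_rep)) {
    stop_param("repeated-sequence T0 is required as the percentage denominator")
  }
  rows <- lapply(seq_len(nrow(eps)), function(i) {
    vals <- vapply(DELTA_PAIRS, function(p) eps[[p[1]]][i] - eps[[p[2]]][i],
                   numeric(1))
    tibble::tibble(sequence_type = eps$sequence_type[i],
                   pair = vapply(DELTA_PAIRS, paste, character(1), collapse = "-"),
                   delta_deg = vals,
                   delta_pct = 100 * vals / t0_rep)
  })
  dplyr::bind_rows(rows)
}

#' Cohort-level endpoints table
#'
#' @param timelines List of [performance_timeline()] objects.
#' @param sequence Sequence type whose endpoints are tabulated.
#' @return Tibble: subject, T0..T5.
#' @export
endpoints_table <- function(timelines, sequence = "repeated") {
  dplyr::bind_rows(lapply(timelines, function(tl) {
    row <- tl$endpoints[tl$endpoints$sequence_type == sequence, ]
    tibble::tibble(subject = tl$subject, row[setdiff(names(row), "sequence_type")])
  }))
}
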