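#' Null calibration of the stepwise + LOOCV + permutation procedure
#'
#' Monte-Carlo study of the full prediction procedure under the global null:
#' all candidate predictors independent of the response. Each repeat draws
#' fresh Gaussian data, runs leave-one-out stepwise prediction and a
#' permutation test, and records the p-value. A calibrated procedure
#' rejects at `alpha` about `alpha` of the time (slightly less, because of
#' the add-one permutation convention).
#'
#' @param n_reps Monte-Carlo repeats.
#' @param n Subjects per repeat.
#' @param n_candidates Candidate predictors.
#' @param n_perm Permutations per repeat.
#' @param alpha Nominal level.
#' @param seed Seed for the whole study.
#' @return List with `rejection_rate`, `pvalues`, `alpha`, `n_reps`.
#' @export
null_calibration_study <- function(n_reps = 200, n = 16, n_candidates = 15,
                                   n_perm = 100, alpha = 0.05, seed = 1) {
  pvals <- with_seed(seed, {
    vapply(seq_len(n_reps), function(b) {
      X <- matrix(rnorm(n * n_candidates), n, n_candidates)
      colnames(X) <- paste0("x", seq_len(n_candidates))
      y <- rnorm(n)
      as.numeric(permutation_pvalue(X, y, n_perm = n_perm))
    }, numeric(1))
  })
  list(rejection_rate = mean(pvals < alpha), pvalues = pvals,
       alpha = alpha, n_reps = n_reps)
}

#' Recovery-study cohort specification
#'
#' The patient-only cohort used by the end-to-end parameter-recovery study:
#' 16 patients, EEG restricted to the pooled sensorimotor channels, 48
#' trials per session at 80 Hz over a -1..7.5 s epoch. These sizes keep a
#' 200-cohort study tractable on one CPU while retaining ~0.95 measurement
#' reliability for the beta measures.
#'
#' @param seed Cohort seed.
#' @param n_patients,n_trials,eeg_fs,epoch_window See [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
recovery_cohort_spec <- function(seed, n_patients = 16, n_trials = 48,
                                 eeg_fs = 80, epoch_window = c(-1, 7.5)) {
  cohort_spec(n_patients = n_patients, n_controls = 0, seed = seed,
              n_trials = n_trials, eeg_fs = eeg_fs,
              epoch_window = epoch_window,
              channels = pool_channels(electrode_pools()))
}

#' End-to-end recovery of the planted PMBR effect
#'
#' Simulates cohorts carrying the planted contralateral-Post1-PMBR to T4
#' association (standardized slope 0.3 plus prior-performance, sleep and
#' hand-dominance confounds), runs the full pipeline (tracking simulation,
#' RMSE scoring, corrected endpoints, EEG simulation, Morlet beta measures,
#' stepwise selection) and reports how often the planted predictor is
#' selected and with the correct (positive) sign.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param seed Base seed; cohort b uses a child seed derived from it.
#' @param freqs Analysis frequency grid for the beta measures.
#' @param ... Passed to [recovery_cohort_spec()].
#' @return List with `selection_rate`, `sign_rate` (correct-sign fraction
#'   among selections), `n_cohorts`, and per-cohort tibble `details`.
#' @export
recovery_study <- function(n_cohorts = 200, seed = 1,
                           freqs = measure_freqs(), ...) {
  rows <- lapply(seq_len(n_cohorts), function(b) {
    spec <- recovery_cohort_spec(seed = child_seed(seed, paste0("cohort", b)),
                                 ...)
    ch <- generate_cohort(spec)
    ep <- endpoints_table(cohort_timelines(ch), "repeated")
    bm <- cohort_beta_measures(ch, sessions = c("Pre", "Post1"),
                               freqs = freqs)
    cand <- candidate_table(ep, bm, ch$covariates, target = "T4")
    keep <- vapply(cand$X, function(col) sd(col) > 0, logical(1))
    X <- as.matrix(zscore_table(cand$X[keep]))
    y <- as.numeric(scale(cand$y))
    m <- stepwise_regression(X, y)
    hit <- "pmbr_contralateral_Post1" %in% m$selected
    tibble::tibble(
      cohort = b, selected = hit,
      beta = if (hit) m$beta[["pmbr_contralateral_Post1"]] else NA_real_,
      r_squared = m$r_squared, n_selected = length(m$selected))
  })
  details <- dplyr::bind_rows(rows)
  sel <- details$selected
  list(selection_rate = mean(sel),
       sign_rate = if (any(sel)) mean(details$beta[sel] > 0) else NA_real_,
       n_cohorts = n_cohorts, details = details)
}

#' Closed-form calibration of the MRBD estimate
#'
#' Runs the Morlet pipeline on synthetic epochs whose movement-window
#' amplitude is scaled by `s` and returns the extracted MRBD next to the
#' closed form `100 (s^2 - 1)`. `noisy = FALSE` uses a noiseless 20 Hz
#' sinusoid; `noisy = TRUE` the default band-limited source with 1/f
#' background at `n_trials` trials.
#'
#' @param s Amplitude scaling in the movement window (`1 + mrbd_depth`).
#' @param noisy Include the stochastic source and 1/f background.
#' @param n_trials Trials (used in the noisy condition).
#' @param seed Seed.
#' @return List with `mrbd` (mean over hemispheres), `expected`, `error`.
#' @export
mrbd_calibration <- function(s, noisy = FALSE, n_trials = 100, seed = 1) {
  op <- if (noisy) {
    oscillation_params(mrbd_depth = s - 1, pmbr_gain = 0)
  } else {
    oscillation_params(beta_bw = 0, noise_sd = 0, mrbd_depth = s - 1,
                       pmbr_gain = 0)
  }
  ep <- simulate_eeg_session(op, n_trials = if (noisy) n_trials else 1,
                             fs = 300,
                             channels = pool_channels(electrode_pools()),
                             seed = seed)
  bm <- session_beta_measures(ep, freqs = coarse_freqs())
  expected <- 100 * (s^2 - 1)
  list(mrbd = mean(bm$mrbd), expected = expected,
       error = mean(bm$mrbd) - expected)
}
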