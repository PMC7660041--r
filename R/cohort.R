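parse_predictor <- function(label) {
  m <- regmatches(label, regexec(
    "^(baseline_beta|mrbd|pmbr)_(contralateral|ipsilateral)_(\\w+)$", label))[[1]]
  if (!length(m)) {
    stop_param("prediction_effect predictor '", label,
               "' is not of the form measure_hemisphere_session")
  }
  list(measure = m[2], hemisphere = m[3], session = m[4])
}

#' Generate a synthetic cohort
#'
#' Draws covariates, per-subject latent traits and oscillation parameters,
#' simulates all tracking sessions (training 40 blocks, retest1 5, retest2
#' 10), and wires the planted prediction effect: the target endpoint's
#' session mean is shifted by `scale_deg` times a standardized linear
#' combination of the planted beta predictor, the confounds and residual
#' noise. EEG epochs are not materialized here; [subject_epochs()] simulates
#' them deterministically on demand from the stored parameters and child
#' seeds.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` object: list with `spec`, `covariates` (tibble),
#'   `behavior` (per-subject list of `tracking_block` lists),
#'   `osc` (tibble of per subject/session/hemisphere oscillation
#'   parameters), and `ground_truth` (latents, shifts and the spec).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_param("`spec` must be a cohort_spec")
  with_seed(spec$seed, {
    ids <- c(sprintf("p%02d", seq_len(spec$n_patients)),
             if (spec$n_controls > 0) sprintf("c%02d", seq_len(spec$n_controls)))
    group <- c(rep("patients", spec$n_patients),
               rep("controls", spec$n_controls))
    n <- length(ids)

    covariates <- tibble::tibble(
      subject = ids, group = group,
      trained_hand = sample(c("left", "right"), n, replace = TRUE),
      hand_dominance = rbinom(n, 1, 0.5),
      age = round(rnorm(n, ifelse(group == "patients", 64, 68),
                        ifelse(group == "patients", 8, 5))),
      sleep_quantity = rnorm(n, ifelse(group == "patients", 7, 6),
                             ifelse(group == "patients", 1.02, 0.94)),
      sleep_quality = rnorm(n, ifelse(group == "patients", 4.7, 5.2),
                            ifelse(group == "patients", 1.57, 0.87)),
      grip_strength = rnorm(n, ifelse(group == "patients", 66, 63),
                            ifelse(group == "patients", 26, 21)),
      nhpt = rnorm(n, ifelse(group == "patients", 0.57, 0.60),
                   ifelse(group == "patients", 0.13, 0.07)),
      sart = rnorm(n, 13, ifelse(group == "patients", 9, 10.7)))

    ability <- rnorm(n)
    # per subject/session/hemisphere oscillation deviations (z units)
    osc_rows <- list()
    amp_z <- matrix(rnorm(n * 2), n, 2,
                    dimnames = list(ids, c("left", "right")))  # stable trait
    for (i in seq_len(n)) {
      for (s in spec$sessions) {
        for (h in c("left", "right")) {
          tmpl <- spec$osc_params[[group[i]]][[s]][[h]]
          z_m <- rnorm(1); z_p <- rnorm(1)
          osc_rows[[length(osc_rows) + 1]] <- tibble::tibble(
            subject = ids[i], session = s, hemisphere = h,
            beta_freq = tmpl$beta_freq, beta_bw = tmpl$beta_bw,
            baseline_amp = tmpl$baseline_amp *
              exp(spec$subject_sd[["baseline_amp"]] * amp_z[i, h]),
            mrbd_depth = max(-1, min(0, tmpl$mrbd_depth +
                                       spec$subject_sd[["mrbd"]] * z_m)),
            pmbr_gain = max(0, tmpl$pmbr_gain + spec$subject_sd[["pmbr"]] * z_p),
            z_mrbd = z_m, z_pmbr = z_p)
        }
      }
    }
    osc <- dplyr::bind_rows(osc_rows)

    # planted endpoint shifts (degrees)
    pe <- spec$prediction_effect
    eps1 <- rnorm(n); eps2 <- rnorm(n)
    z_sleep <- (covariates$sleep_quantity -
                  ifelse(group == "patients", 7, 6)) /
      ifelse(group == "patients", 1.02, 0.94)
    z_hand <- (covariates$hand_dominance - 0.5) / 0.5
    if (!is.null(pe)) {
      pp <- parse_predictor(pe$predictor)
      if (!pp$session %in% spec$sessions) {
        stop_param("prediction_effect session '", pp$session,
                   "' is not a generated session")
      }
      if (!pe$target %in% c("T2", "T3", "T4", "T5")) {
        stop_param("prediction_effect target '", pe$target,
                   "' is not a generated endpoint")
      }
      z_pred <- vapply(seq_len(n), function(i) {
        side <- hemisphere_map(covariates$trained_hand[i])[[pp$hemisphere]]
        row <- osc$subject == ids[i] & osc$session == pp$session &
          osc$hemisphere == side
        osc[[paste0("z_", pp$measure)]][row]
      }, numeric(1))
      cf <- pe$confounds
      lin <- pe$slope * z_pred +
        (cf[["prior_performance"]] %||% 0) * ability +
        (cf[["sleep_quantity"]] %||% 0) * z_sleep +
        (cf[["hand_dominance"]] %||% 0) * z_hand +
        pe$noise_sd * eps2
      planted_session <- if (pe$target %in% c("T2", "T3")) "retest1" else "retest2"
      sc <- pe$scale_deg
    } else {
      z_pred <- rep(NA_real_, n); lin <- eps2
      planted_session <- "retest2"
      sc <- 0
      cf <- c(prior_performance = 0)
    }
    prior_slope <- if (!is.null(pe)) (pe$confounds[["prior_performance"]] %||% 0) else 0
    rn <- spec$subject_sd[["retest_noise"]]
    shift_r1 <- (if (planted_session == "retest1") sc * lin else
                   sc * (prior_slope * ability + rn * eps1))
    shift_r2 <- (if (planted_session == "retest2") sc * lin else
                   sc * (prior_slope * ability + rn * eps1))

    behavior <- vector("list", n)
    names(behavior) <- ids
    for (i in seq_len(n)) {
      bp <- spec$behavior_params[[group[i]]]
      wp <- runif(12, -bp$range_deg, bp$range_deg)
      behavior[[i]] <- c(
        simulate_tracking_session(bp, SESSION_BLOCKS[["training"]], "training",
                                  0L, 0, wp, ids[i],
                                  seed = child_seed(spec$seed, paste0(ids[i], "-tr"))),
        simulate_tracking_session(bp, SESSION_BLOCKS[["retest1"]], "retest1",
                                  40L, shift_r1[i], wp, ids[i],
                                  seed = child_seed(spec$seed, paste0(ids[i], "-r1"))),
        simulate_tracking_session(bp, SESSION_BLOCKS[["retest2"]], "retest2",
                                  45L, shift_r2[i], wp, ids[i],
                                  seed = child_seed(spec$seed, paste0(ids[i], "-r2"))))
    }

    ground_truth <- list(
      spec = spec,
      latents = tibble::tibble(subject = ids, ability = ability,
                               z_planted_predictor = z_pred,
                               shift_retest1_deg = shift_r1,
                               shift_retest2_deg = shift_r2),
      planted = pe)
    structure(list(spec = spec, covariates = covariates, behavior = behavior,
                   osc = osc, ground_truth = ground_truth),
              class = "cohort")
  })
}

#' Materialize one subject/session's EEG epochs
#'
#' Simulates the cue-aligned epochs for a subject and EEG session from the
#' cohort's stored per-hemisphere oscillation parameters, deterministically
#' (child seed derived from the cohort seed and the subject/session key).
#'
#' @param cohort A [generate_cohort()] result.
#' @param subject Subject id.
#' @param session EEG session label (`"Pre"`, `"Post1"`, `"Post2"`).
#' @return An `epoch_set`.
#' @export
subject_epochs <- function(cohort, subject, session) {
  spec <- cohort$spec
  if (!subject %in% cohort$covariates$subject) {
    stop_param("unknown subject '", subject, "'")
  }
  if (!session %in% spec$sessions) stop_param("unknown session '", session, "'")
  group <- cohort$covariates$group[cohort$covariates$subject == subject]
  pars <- list()
  for (h in c("left", "right")) {
    row <- cohort$osc[cohort$osc$subject == subject &
                        cohort$osc$session == session &
                        cohort$osc$hemisphere == h, ]
    tmpl <- spec$osc_params[[group]][[session]][[h]]
    tmpl$baseline_amp <- row$baseline_amp
    tmpl$mrbd_depth <- row$mrbd_depth
    tmpl$pmbr_gain <- row$pmbr_gain
    pars[[h]] <- tmpl
  }
  simulate_eeg_session(pars, n_trials = spec$n_trials, fs = spec$eeg_fs,
                       epoch_window = spec$epoch_window,
                       channels = spec$channels,
                       seed = child_seed(spec$seed, paste0(subject, "-eeg-", session)))
}

#' Score every subject's tracking data
#'
#' @param cohort A [generate_cohort()] result.
#' @return List of [performance_timeline()] objects, one per subject.
#' @export
cohort_timelines <- function(cohort) {
  lapply(cohort$behavior, performance_timeline)
}

#' Beta measures for every subject and EEG session
#'
#' Materializes each subject/session epoch set and extracts the six beta
#' parameters (baseline power, MRBD, PMBR per hemisphere) with
#' [session_beta_measures()]. Sessions are processed one at a time so the
#' full cohort never resides in memory.
#'
#' @param cohort A [generate_cohort()] result.
#' @param sessions EEG sessions to process (default all).
#' @param freqs Analysis frequency grid.
#' @param time_points Epoch times at which power is evaluated (fast raster
#'   by default; `NULL` for the full time axis).
#' @param pools An [electrode_pools()] object.
#' @return Tidy tibble: subject, session, hemisphere, baseline_beta, mrbd,
#'   pmbr.
#' @export
cohort_beta_measures <- function(cohort, sessions = cohort$spec$sessions,
                                 freqs = measure_freqs(),
                                 time_points = beta_time_points(),
                                 pools = electrode_pools()) {
  rows <- list()
  for (id in cohort$covariates$subject) {
    hand <- cohort$covariates$trained_hand[cohort$covariates$subject == id]
    for (s in sessions) {
      ep <- subject_epochs(cohort, id, s)
      rows[[length(rows) + 1]] <- session_beta_measures(
        ep, pools = pools, trained_hand = hand, freqs = freqs,
        time_points = time_points, subject = id, session = s)
    }
  }
  dplyr::bind_rows(rows)
}
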