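#' Behavioural learning-curve parameters
#'
#' Parameters of the closed-form block-level learning curve used by the
#' tracking-task simulator. The mean block RMSE (in degrees of wrist angle)
#' for cumulative block number \eqn{b} is
#' \deqn{m(b) = initial - A_s (1 - e^{-rate \cdot b}) + fatigue \cdot \max(0, b - b_{onset})}
#' with \eqn{A_s = amplitude (1 + gain)} for the repeated sequence and
#' \eqn{A_s = amplitude} for random sequences. Fatigue accrues during the
#' training session only. Retest sessions apply a multiplicative offline
#' boost (both sequences) and, for retest2, multiplicative overnight
#' forgetting (repeated sequence only).
#'
#' @param initial_rmse Mean block RMSE before any learning, degrees (> 0).
#' @param learning_amplitude Asymptotic general improvement, degrees (>= 0).
#' @param learning_rate Exponential rate per block (>= 0).
#' @param sequence_gain Fractional extra improvement for the repeated
#'   sequence, in `[0, 1]`.
#' @param fatigue_slope Late-training performance decrement, degrees/block.
#' @param fatigue_onset Cumulative block after which fatigue accrues.
#' @param offline_boost Fractional RMSE drop between training and retests,
#'   in `[0, 1]`.
#' @param overnight_forgetting Fractional RMSE rise overnight (repeated
#'   sequence only), in `[0, 1]`.
#' @param noise_sd SD of the block-level perturbation of the RMSE mean,
#'   degrees (>= 0).
#' @param block_duration Duration of one sequence presentation, seconds.
#' @param sample_rate Behavioural sampling rate, Hz.
#' @param range_deg Half-range of wrist excursion used for target
#'   trajectories, degrees.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(initial_rmse = 10,
                            learning_amplitude = 0.6,
                            learning_rate = 0.08,
                            sequence_gain = 0.5,
                            fatigue_slope = 0.04,
                            fatigue_onset = 30,
                            offline_boost = 0.07,
                            overnight_forgetting = 0.10,
                            noise_sd = 0.3,
                            block_duration = 18,
                            sample_rate = 20,
                            range_deg = 25) {
  check_number(initial_rmse, "initial_rmse", lower = 1e-12)
  check_number(learning_amplitude, "learning_amplitude", lower = 0)
  check_number(learning_rate, "learning_rate", lower = 0)
  check_number(sequence_gain, "sequence_gain", lower = 0, upper = 1)
  check_number(fatigue_slope, "fatigue_slope", lower = 0)
  check_number(fatigue_onset, "fatigue_onset", lower = 0)
  check_number(offline_boost, "offline_boost", lower = 0, upper = 1)
  check_number(overnight_forgetting, "overnight_forgetting", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(block_duration, "block_duration", lower = 0.5)
  check_number(sample_rate, "sample_rate", lower = 1)
  check_number(range_deg, "range_deg", lower = 1)
  structure(as.list(environment()), class = "behavior_params")
}

#' Oscillatory EEG source parameters for one hemisphere
#'
#' Describes the sensorimotor beta source feeding the synthetic EEG
#' generator: a band-limited beta oscillation whose amplitude envelope drops
#' by `mrbd_depth` during the movement window and rises by `pmbr_gain` in the
#' post-movement rebound window, mixed into channels by a topography peaked
#' over the sensorimotor electrode pools, on top of 1/f background noise.
#'
#' @param beta_freq Centre frequency of the beta source, Hz (15-30 unless
#'   `override_band`).
#' @param beta_bw Full bandwidth of the stochastic beta source, Hz. `0`
#'   selects a pure sinusoid at `beta_freq` (used for closed-form checks).
#' @param baseline_amp RMS amplitude of the beta source at baseline, signal
#'   units (microvolts); > 0.
#' @param mrbd_depth Relative amplitude change in the movement window, in
#'   `[-1, 0]`; power changes by `(1 + mrbd_depth)^2 - 1`.
#' @param pmbr_gain Relative amplitude change in the rebound window, >= 0.
#' @param background_exponent Spectral exponent of the 1/f background.
#' @param noise_sd RMS amplitude of the background noise per channel,
#'   microvolts; `0` disables noise.
#' @param movement_window,rebound_window Envelope windows, seconds relative
#'   to the cue.
#' @param ramp Raised-cosine envelope transition length, seconds.
#' @param topography Optional named numeric vector of per-channel source
#'   weights (>= 0); defaults to the built-in sensorimotor topography.
#' @param override_band Allow `beta_freq` outside 15-30 Hz.
#' @return An object of class `oscillation_params`.
#' @export
oscillation_params <- function(beta_freq = 20,
                               beta_bw = 20,
                               baseline_amp = 8,
                               mrbd_depth = -0.35,
                               pmbr_gain = 0.25,
                               background_exponent = 1,
                               noise_sd = 3,
                               movement_window = c(0.5, 4.5),
                               rebound_window = c(5.5, 8.0),
                               ramp = 0.25,
                               topography = NULL,
                               override_band = FALSE) {
  if (!override_band) check_number(beta_freq, "beta_freq", lower = 15, upper = 30)
  check_number(beta_bw, "beta_bw", lower = 0)
  check_number(baseline_amp, "baseline_amp", lower = 1e-12)
  check_number(mrbd_depth, "mrbd_depth", lower = -1, upper = 0)
  check_number(pmbr_gain, "pmbr_gain", lower = 0)
  check_number(background_exponent, "background_exponent", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(movement_window, "movement_window", len = 2L)
  check_number(rebound_window, "rebound_window", len = 2L)
  check_number(ramp, "ramp", lower = 0)
  if (!is.null(topography)) {
    if (is.null(names(topography)) || any(topography < 0)) {
      stop_param("`topography` must be a named vector of non-negative weights")
    }
  }
  structure(as.list(environment()), class = "oscillation_params")
}

#' Planted prediction effect
#'
#' A known linear association injected into synthetic cohorts between a beta
#' measure (default: contralateral PMBR after training, session Post1) and a
#' future performance endpoint (default: T4, start of the 24-h retest).
#' Slopes are standardized: the target endpoint receives a between-subject
#' shift of `scale_deg` times a unit-variance linear combination of the
#' z-scored predictor, confounds and residual noise.
#'
#' @param target Endpoint label receiving the effect (`"T4"`).
#' @param predictor Beta-measure label, `"pmbr_contralateral_Post1"`.
#' @param slope Standardized slope of the predictor.
#' @param confounds Named standardized slopes for
#'   `prior_performance` (latent learning ability, also visible in T2/T3),
#'   `sleep_quantity` and `hand_dominance`.
#' @param noise_sd Standardized residual SD of the latent endpoint model.
#' @param scale_deg Between-subject SD scale of the endpoint shift, degrees.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(target = "T4",
                           predictor = "pmbr_contralateral_Post1",
                           slope = 0.3,
                           confounds = c(prior_performance = 0.85,
                                         sleep_quantity = -0.16,
                                         hand_dominance = 0.13),
                           noise_sd = 0.10,
                           scale_deg = 2.0) {
  check_number(slope, "slope")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(scale_deg, "scale_deg", lower = 0)
  if (length(confounds) && is.null(names(confounds))) {
    stop_param("`confounds` must be a named numeric vector")
  }
  structure(as.list(environment()), class = "planted_effect")
}

#' Cohort specification for the synthetic-data generator
#'
#' Defines a two-group cohort (stroke patients and healthy controls) with a
#' single training session (40 blocks), retest1 (5 blocks), retest2
#' (10 blocks), and EEG sessions Pre/Post1/Post2 around the training phase.
#'
#' @param n_patients,n_controls Group sizes (>= 1; `n_controls` may be 0 for
#'   patient-only studies).
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @param sessions EEG session labels, default `c("Pre", "Post1", "Post2")`.
#' @param behavior_params A [behavior_params()] object, or a named list with
#'   entries `patients` and `controls`.
#' @param osc_params An [oscillation_params()] object used as template for
#'   every group/session/hemisphere, or a nested named list
#'   `osc_params[[group]][[session]][[hemisphere]]` of such objects
#'   (hemispheres `"left"`/`"right"`).
#' @param prediction_effect A [planted_effect()] object, or `NULL` for none.
#' @param n_trials Trials per EEG session (paper task: 120).
#' @param eeg_fs EEG sampling rate, Hz (post-downsampling rate: 300).
#' @param epoch_window Epoch window in seconds relative to the cue.
#' @param channels Channel label set for generated EEG; defaults to the
#'   64-channel 10-10 montage, [montage_64()].
#' @param subject_sd Named vector of between-subject SDs:
#'   `mrbd` and `pmbr` (amplitude-fraction units), `baseline_amp`
#'   (log-normal sigma), `retest_noise` (session-level residual, standardized).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16,
                        n_controls = 20,
                        seed = 1,
                        sessions = c("Pre", "Post1", "Post2"),
                        behavior_params = default_behavior_params(),
                        osc_params = oscillation_params(),
                        prediction_effect = planted_effect(),
                        n_trials = 120,
                        eeg_fs = 300,
                        epoch_window = c(-1, 9),
                        channels = montage_64(),
                        subject_sd = c(mrbd = 0.10, pmbr = 0.10,
                                       baseline_amp = 0.2, retest_noise = 0.10)) {
  n_patients <- check_count(n_patients, "n_patients", lower = 1L)
  n_controls <- check_count(n_controls, "n_controls", lower = 0L)
  check_count(seed, "seed", lower = -2147483647)
  if (anyDuplicated(sessions)) stop_param("`sessions` labels must be unique")
  n_trials <- check_count(n_trials, "n_trials", lower = 1L)
  check_number(eeg_fs, "eeg_fs", lower = 1)
  check_number(epoch_window, "epoch_window", len = 2L)
  if (inherits(behavior_params, "behavior_params")) {
    behavior_params <- list(patients = behavior_params,
                            controls = control_behavior(behavior_params))
  }
  stopifnot(all(c("patients", "controls") %in% names(behavior_params)))
  if (inherits(osc_params, "oscillation_params")) {
    osc_params <- default_osc_grid(osc_params, sessions)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

default_behavior_params <- function() behavior_params()

# Controls learn faster / more than patients; same task parameters otherwise.
control_behavior <- function(bp, amplitude_ratio = 2.0, fatigue_ratio = 0.5) {
  bp$learning_amplitude <- bp$learning_amplitude * amplitude_ratio
  bp$fatigue_slope <- bp$fatigue_slope * fatigue_ratio
  bp
}

# Expand one template into the group x session x hemisphere grid.
# Controls show a transient post-training rise in baseline beta at Post1 and
# small training-related MRBD/PMBR reductions; patients do not.
default_osc_grid <- function(template, sessions) {
  grid <- list()
  for (group in c("patients", "controls")) {
    grid[[group]] <- list()
    for (s in sessions) {
      pars <- template
      if (group == "controls") {
        if (s == "Post1") pars$baseline_amp <- pars$baseline_amp * 1.15
        if (s %in% c("Post1", "Post2")) {
          pars$mrbd_depth <- pars$mrbd_depth * 0.9
          pars$pmbr_gain <- pars$pmbr_gain * 0.9
        }
      }
      grid[[group]][[s]] <- list(left = pars, right = pars)
    }
  }
  grid
}
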