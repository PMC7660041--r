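#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end run uses. Windows must
#' lie inside the epoch, analysis bands inside 5-45 Hz, and stepwise alphas
#' in (0, 1).
#'
#' @param cohort A [cohort_spec()] (synthetic mode) or `NULL` when reading
#'   data from `in_dir`.
#' @param in_dir Directory of EDF + behaviour CSV inputs (real-data mode).
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param freqs Analysis frequency grid, Hz.
#' @param time_points Epoch times for power evaluation (`NULL` = full axis).
#' @param pools [electrode_pools()].
#' @param mrbd_window,mrbd_band,pmbr_window,pmbr_band,baseline Analysis
#'   windows (s) and bands (Hz).
#' @param reject_threshold Peak-to-peak artifact threshold, microvolts.
#' @param alpha_enter,alpha_exclude Stepwise thresholds.
#' @param n_perm Permutations for the prediction p-value.
#' @param target Endpoint to predict.
#' @param seed Seed for the inference stage's permutation stream.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            in_dir = NULL, out_dir = NULL,
                            freqs = measure_freqs(),
                            time_points = beta_time_points(),
                            pools = electrode_pools(),
                            mrbd_window = c(1, 2), mrbd_band = c(15, 30),
                            pmbr_window = c(6, 7), pmbr_band = c(10, 25),
                            baseline = c(-0.9, 0),
                            reject_threshold = 150,
                            alpha_enter = 0.05, alpha_exclude = 0.1,
                            n_perm = 100, target = "T4", seed = 1) {
  epoch <- if (!is.null(cohort)) cohort$epoch_window else c(-1, 9)
  for (w in list(mrbd_window, pmbr_window, baseline)) {
    if (w[1] < epoch[1] || w[2] > epoch[2]) {
      stop_param("analysis window [", w[1], ", ", w[2],
                 "] lies outside the epoch [", epoch[1], ", ", epoch[2], "]")
    }
  }
  for (b in list(mrbd_band, pmbr_band)) {
    if (b[1] < 5 || b[2] > 45) {
      stop_param("analysis band [", b[1], ", ", b[2], "] outside 5-45 Hz")
    }
  }
  check_number(alpha_enter, "alpha_enter", lower = 1e-12, upper = 1 - 1e-12)
  check_number(alpha_exclude, "alpha_exclude", lower = 1e-12, upper = 1 - 1e-12)
  check_count(n_perm, "n_perm", lower = 1L)
  check_count(seed, "seed", lower = -2147483647)
  cfg <- structure(as.list(environment())[c(
    "cohort", "in_dir", "out_dir", "freqs", "time_points", "pools",
    "mrbd_window", "mrbd_band", "pmbr_window", "pmbr_band", "baseline",
    "reject_threshold", "alpha_enter", "alpha_exclude", "n_perm", "target",
    "seed")], class = "pipeline_config")
  cfg$hash <- config_hash(unclass(cfg))
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_param("[stage ", name, "] ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: generate the cohort, score tracking behaviour into
#' endpoint tables, extract beta measures per subject/session/hemisphere,
#' run the group-level mixed ANOVAs (performance: group x sequence x time
#' T0-T4; beta measures: group x hemisphere x session), and fit the
#' endpoint prediction model with LOOCV and permutation testing. Every
#' written table carries the configuration hash; a JSON summary and log
#' are written when `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `config`, `cohort`, `timelines`,
#'   `endpoints` (repeated + random), `deltas`, `beta`, `anova_performance`,
#'   `anova_beta`, `prediction`, `summary`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_param("`config` must come from pipeline_config()")
  }
  cohort <- stage("simulate", {
    if (is.null(config$cohort)) stop_param("real-data mode requires in_dir reading; see read_eeg()")
    generate_cohort(config$cohort)
  })
  timelines <- stage("behavior", cohort_timelines(cohort))
  endpoints <- stage("behavior", list(
    repeated = endpoints_table(timelines, "repeated"),
    random = endpoints_table(timelines, "random")))
  deltas <- stage("behavior", dplyr::bind_rows(lapply(timelines, function(tl) {
    tibble::tibble(subject = tl$subject, delta_performance(tl))
  })))
  beta <- stage("spectral", cohort_beta_measures(
    cohort, freqs = config$freqs, time_points = config$time_points,
    pools = config$pools))

  anova_perf <- stage("inference", {
    long <- dplyr::bind_rows(lapply(names(endpoints), function(seqt) {
      ep <- endpoints[[seqt]]
      tidyr::pivot_longer(ep, cols = dplyr::all_of(c("T0", "T1", "T2", "T3", "T4")),
                          names_to = "time", values_to = "rmse") |>
        dplyr::mutate(sequence_type = seqt)
    }))
    long <- dplyr::inner_join(long,
                              cohort$covariates[c("subject", "group")],
                              by = "subject")
    between <- if (length(unique(long$group)) > 1) "group" else NULL
    mixed_anova(long, dv = "rmse", between = between,
                within = c("sequence_type", "time"))
  })
  anova_beta <- stage("inference", {
    bt <- dplyr::inner_join(beta, cohort$covariates[c("subject", "group")],
                            by = "subject")
    between <- if (length(unique(bt$group)) > 1) "group" else NULL
    lapply(c(baseline_beta = "baseline_beta", mrbd = "mrbd", pmbr = "pmbr"),
           function(m) mixed_anova(bt, dv = m, between = between,
                                   within = c("hemisphere", "session")))
  })
  prediction <- stage("inference", {
    cand <- candidate_table(endpoints$repeated, beta, cohort$covariates,
                            target = config$target)
    predict_performance(cand, n_perm = config$n_perm, seed = config$seed,
                        alpha_enter = config$alpha_enter,
                        alpha_exclude = config$alpha_exclude)
  })

  summary <- list(
    config_hash = config$hash,
    seed = config$cohort$seed,
    n_patients = config$cohort$n_patients,
    n_controls = config$cohort$n_controls,
    endpoints_mean_repeated = colMeans(endpoints$repeated[-1]),
    anova_performance = as.data.frame(anova_perf),
    prediction = list(selected = prediction$selected,
                      beta = as.list(prediction$beta),
                      r_squared = prediction$r_squared,
                      loocv_r = prediction$r,
                      p_permutation = prediction$p_permutation,
                      semipartial_r2 = prediction$semipartial_r2))
  result <- structure(list(config = config, cohort = cohort,
                           timelines = timelines, endpoints = endpoints,
                           deltas = deltas, beta = beta,
                           anova_performance = anova_perf,
                           anova_beta = anova_beta, prediction = prediction,
                           summary = summary),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

# Write tables (each with the config hash as a column), the JSON summary
# and a run log.
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- result$config$hash
  wr <- function(tab, name) {
    tab$config_hash <- h
    utils::write.csv(tab, file.path(out_dir, name), row.names = FALSE)
  }
  wr(result$endpoints$repeated, "endpoints_repeated.csv")
  wr(result$endpoints$random, "endpoints_random.csv")
  wr(result$deltas, "deltas.csv")
  wr(result$beta, "beta_measures.csv")
  wr(result$anova_performance, "anova_performance.csv")
  wr(result$cohort$covariates, "covariates.csv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ver <- tryCatch(as.character(utils::packageVersion("betalearn")),
                  error = function(e) "dev")
  log <- c(paste("betalearn", ver),
           paste("R", getRversion()),
           paste("seed", result$config$cohort$seed),
           paste("config_hash", h),
           paste("finished", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(result)
}

#' Join two pipeline tables, refusing mixed provenance
#'
#' Tables written by [run_pipeline()] carry a `config_hash` column; joining
#' tables produced under different configurations is refused.
#'
#' @param x,y Data frames with `config_hash` columns.
#' @param by Join keys passed to [dplyr::inner_join()].
#' @return Joined tibble.
#' @export
join_checked <- function(x, y, by = "subject") {
  hx <- unique(x$config_hash)
  hy <- unique(y$config_hash)
  if (length(hx) != 1 || length(hy) != 1 || is.na(hx) || is.na(hy)) {
    stop_param("tables must carry exactly one config_hash each")
  }
  if (hx != hy) {
    stop_param("refusing to join tables from different pipeline runs ",
               "(config hashes ", substr(hx, 1, 8), " vs ", substr(hy, 1, 8), ")")
  }
  dplyr::inner_join(x, dplyr::select(y, -"config_hash"), by = by)
}
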