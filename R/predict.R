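#' Assemble the candidate predictor table for endpoint prediction
#'
#' Joins behavioral endpoints, beta measures (sessions Pre and Post1, both
#' hemispheres, as `measure_hemisphere_session` columns) and demographic /
#' clinical covariates on subject id. The candidate set follows the study
#' design: earlier endpoints (T0-T1 for a T2 model, T0-T3 for a T4 model),
#' the six beta parameters at Pre and at Post1, age, affected-hand
#' dominance, sleep quantity and quality, grip strength, NHPT and SART.
#'
#' @param endpoints Tibble from [endpoints_table()].
#' @param beta Tidy beta-measures tibble ([cohort_beta_measures()]).
#' @param covariates Covariate tibble (one row per subject).
#' @param target Endpoint to predict, `"T2"` or `"T4"`.
#' @param group Restrict to one group (default `"patients"`); `NULL` keeps
#'   everyone.
#' @return List with `y` (response vector), `X` (tibble of candidates) and
#'   `subjects`.
#' @export
candidate_table <- function(endpoints, beta, covariates, target = "T4",
                            group = "patients") {
  if (!target %in% c("T2", "T4")) stop_param("target must be 'T2' or 'T4'")
  beta_sessions <- intersect(c("Pre", "Post1"), unique(beta$session))
  wide <- beta[beta$session %in% beta_sessions, ] |>
    tidyr::pivot_longer(cols = c("baseline_beta", "mrbd", "pmbr"),
                        names_to = "measure", values_to = "value") |>
    tidyr::pivot_wider(names_from = c("measure", "hemisphere", "session"),
                       values_from = "value", names_sep = "_")
  tab <- dplyr::inner_join(endpoints, wide, by = "subject") |>
    dplyr::inner_join(covariates, by = "subject")
  if (!is.null(group)) tab <- tab[tab$group == group, ]
  prior <- if (target == "T4") c("T0", "T1", "T2", "T3") else c("T0", "T1")
  demo <- c("age", "hand_dominance", "sleep_quantity", "sleep_quality",
            "grip_strength", "nhpt", "sart")
  beta_cols <- setdiff(names(wide), c("subject", "session"))
  keep <- c(prior, beta_cols, demo)
  missing <- setdiff(keep, names(tab))
  if (length(missing)) {
    stop_param("candidate columns missing from joined table: ",
               paste(missing, collapse = ", "))
  }
  list(y = tab[[target]], X = tab[keep], subjects = tab$subject)
}

#' Predict a future performance endpoint from behaviour and beta measures
#'
#' Z-scores response and candidates, runs stepwise selection on the full
#' sample, evaluates predictive strength by leave-one-out cross-validation
#' (selection re-run within every fold), attaches a permutation p-value for
#' the actual-vs-predicted correlation, and reports the squared
#' semi-partial correlation of a predictor of interest after regressing out
#' prior performance, hand dominance and sleep.
#'
#' @param candidates A [candidate_table()] result.
#' @param n_perm Number of permutations (default 100).
#' @param seed Seed for the permutation stream.
#' @param alpha_enter,alpha_exclude Stepwise thresholds.
#' @param sp_predictor Predictor for the semi-partial follow-up (default
#'   contralateral PMBR at Post1); `NULL` skips it.
#' @param sp_confounds Confound columns for the semi-partial follow-up.
#' @return A `prediction_result`: list with `model` (stepwise fit),
#'   `selected`, `beta`, `r_squared`, `loocv` (per-subject predictions),
#'   `r`, `p_permutation`, `n_perm`, `semipartial_r2`.
#' @export
predict_performance <- function(candidates, n_perm = 100, seed = NULL,
                                alpha_enter = 0.05, alpha_exclude = 0.1,
                                sp_predictor = "pmbr_contralateral_Post1",
                                sp_confounds = c("T2", "T3", "hand_dominance",
                                                 "sleep_quantity")) {
  keep <- vapply(candidates$X, function(col) sd(col) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping constant candidate column(s): ",
            paste(names(candidates$X)[!keep], collapse = ", "))
  }
  X <- as.matrix(zscore_table(candidates$X[keep]))
  y <- as.numeric(scale(candidates$y))
  model <- stepwise_regression(X, y, alpha_enter, alpha_exclude)
  cv <- loocv_predict(X, y, alpha_enter, alpha_exclude)
  p_perm <- permutation_pvalue(X, y, n_perm = n_perm, seed = seed,
                               alpha_enter = alpha_enter,
                               alpha_exclude = alpha_exclude, observed = cv)
  sp <- NA_real_
  if (!is.null(sp_predictor) && sp_predictor %in% colnames(X)) {
    conf <- intersect(sp_confounds, colnames(X))
    sp <- semipartial_r2(y, X[, sp_predictor], X[, conf, drop = FALSE])
  }
  structure(list(model = model, selected = model$selected, beta = model$beta,
                 r_squared = model$r_squared, loocv = cv, r = cv$r,
                 p_permutation = as.numeric(p_perm), n_perm = n_perm,
                 subjects = candidates$subjects,
                 semipartial_r2 = sp, sp_predictor = sp_predictor),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("Endpoint prediction (n =", x$model$n, ")\n")
  print(x$model)
  cat(sprintf("  LOOCV r(actual, predicted) = %.3f, permutation p = %.4f (%d perms)\n",
              x$r, x$p_permutation, x$n_perm))
  if (!is.na(x$semipartial_r2)) {
    cat(sprintf("  semi-partial r^2 of %s = %.3f\n", x$sp_predictor,
                x$semipartial_r2))
  }
  invisible(x)
}
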