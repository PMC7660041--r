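#' Z-score the numeric columns of a table
#'
#' Centres each numeric column to mean 0 and scales to sample SD 1.
#' Non-numeric columns are passed through. Re-application is idempotent.
#'
#' @param tab Data frame or tibble.
#' @return Table of the same shape.
#' @export
zscore_table <- function(tab) {
  out <- tab
  for (nm in names(out)) {
    x <- out[[nm]]
    if (!is.numeric(x)) next
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop_param("column '", nm, "' has zero variance and cannot be Z-scored")
    }
    out[[nm]] <- (x - mean(x)) / s
  }
  out
}

# Least-squares fit with intercept; coefficient t-tests via the QR factor.
# Errors on a numerically collinear predictor set.
fast_lm <- function(X, y, kappa_max = 1e8) {
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    stop_param("selected predictor set is collinear (rank deficient)")
  }
  R <- qr.R(qr_x)
  d <- abs(diag(R))
  if (max(d) / min(d) > kappa_max) {
    stop_param("selected predictor set is collinear (condition number too large)")
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - Xi %*% beta
  df <- n - ncol(Xi)
  s2 <- sum(resid^2) / df
  Rinv <- backsolve(R, diag(ncol(Xi)))
  se <- sqrt(s2 * rowSums(Rinv^2))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  ybar <- mean(y)
  r2 <- if (sum((y - ybar)^2) > 0) 1 - sum(resid^2) / sum((y - ybar)^2) else 0
  list(beta = beta, se = se, t = tval, p = pval, df = df, r_squared = r2,
       fitted = as.numeric(Xi %*% beta))
}

# Core forward/backward selection on a plain matrix. Returns integer column
# indices of the selected set, in entry order.
stepwise_core <- function(X, y, alpha_enter = 0.05, alpha_exclude = 0.1) {
  n <- length(y)
  p <- ncol(X)
  active <- integer(0)
  max_terms <- n - 3L                       # keep df >= 1 for the entry test
  Xc <- X - rep(colMeans(X), each = n)      # intercept-residualized, reused
  yc <- y - mean(y)
  for (iter in seq_len(2L * p + 2L)) {
    changed <- FALSE
    # forward: candidate with the smallest entry p-value (tie: column order)
    cand <- setdiff(seq_len(p), active)
    df <- n - length(active) - 2L
    if (length(cand) && length(active) < max_terms && df >= 1L) {
      if (length(active)) {
        Q <- qr.Q(qr(Xc[, active, drop = FALSE]))
        ry <- yc - Q %*% crossprod(Q, yc)
        RX <- Xc[, cand, drop = FALSE] - Q %*% crossprod(Q, Xc[, cand, drop = FALSE])
      } else {
        ry <- yc
        RX <- Xc
      }
      ssy <- sum(ry^2)
      ssx <- colSums(RX^2)
      ok <- ssx > 1e-10 * n & ssy > 1e-24
      r <- rep(0, length(cand))
      r[ok] <- (crossprod(RX, ry)[, 1] / sqrt(ssx * ssy))[ok]
      r2 <- pmin(r^2, 1)
      tstat <- abs(r) * sqrt(df / pmax(1 - r2, 1e-300))
      pval <- 2 * pt(tstat, df, lower.tail = FALSE)
      pval[!ok] <- 1
      j <- which.min(pval)
      if (pval[j] < alpha_enter) {
        active <- c(active, cand[j])
        changed <- TRUE
      }
    }
    # backward: drop the worst retained predictor with p > alpha_exclude
    while (length(active)) {
      fit <- fast_lm(X[, active, drop = FALSE], y)
      pv <- fit$p[-1]
      worst <- which.max(pv)
      if (pv[worst] > alpha_exclude) {
        active <- active[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  active
}

#' Stepwise multiple linear regression
#'
#' Forward/backward selection: at each step the candidate with the smallest
#' entry p-value is added if below `alpha_enter`, then any retained
#' predictor whose p-value exceeds `alpha_exclude` is removed (worst
#' first), until no change. Ties are broken by column order, making runs
#' deterministic. Predictors are expected Z-scored so coefficients are
#' standardized.
#'
#' @param X Predictor table (data frame or matrix with column names).
#' @param y Response vector.
#' @param alpha_enter Entry threshold on the candidate p-value (default 0.05).
#' @param alpha_exclude Exclusion threshold on retained p-values (default 0.1).
#' @return A `stepwise_model`: list with `selected` (labels), `beta`,
#'   `se`, `t`, `p` (named, intercept included), `r_squared`, `df`, `n`.
#' @export
stepwise_regression <- function(X, y, alpha_enter = 0.05, alpha_exclude = 0.1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop_param("X and y dimensions disagree")
  check_number(alpha_enter, "alpha_enter", lower = 1e-12, upper = 1 - 1e-12)
  check_number(alpha_exclude, "alpha_exclude", lower = 1e-12, upper = 1 - 1e-12)
  active <- stepwise_core(X, y, alpha_enter, alpha_exclude)
  if (length(active)) {
    fit <- fast_lm(X[, active, drop = FALSE], y)
  } else {
    fit <- list(beta = c(`(Intercept)` = mean(y)), se = NA_real_, t = NA_real_,
                p = NA_real_, df = length(y) - 1L, r_squared = 0,
                fitted = rep(mean(y), length(y)))
  }
  structure(list(selected = colnames(X)[active], beta = fit$beta, se = fit$se,
                 t = fit$t, p = fit$p, r_squared = fit$r_squared, df = fit$df,
                 n = length(y), alpha_enter = alpha_enter,
                 alpha_exclude = alpha_exclude),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("Stepwise linear model (alphaEnter ", x$alpha_enter, ", alphaExclude ",
      x$alpha_exclude, ")\n", sep = "")
  if (!length(x$selected)) {
    cat("  no predictors selected\n")
  } else {
    for (nm in x$selected) {
      cat(sprintf("  %-28s beta = %7.3f  t = %6.2f  p = %.4g\n",
                  nm, x$beta[[nm]], x$t[[nm]], x$p[[nm]]))
    }
    cat(sprintf("  R^2 = %.3f on %d obs\n", x$r_squared, x$n))
  }
  invisible(x)
}

#' Leave-one-out cross-validated prediction
#'
#' For each subject the full stepwise selection and fit are re-run on the
#' remaining subjects, the held-out subject is predicted, and the
#' correlation between actual and predicted values is reported. A fold in
#' which no predictor enters predicts the training mean (logged, not an
#' error); selection may differ across folds.
#'
#' @inheritParams stepwise_regression
#' @return A `loocv_result`: list with `predicted`, `actual`, `r`,
#'   `fold_selected` (list of label vectors), `n_empty_folds`,
#'   `degenerate_r` (TRUE when predictions were constant and `r` is
#'   defined as 0).
#' @export
loocv_predict <- function(X, y, alpha_enter = 0.05, alpha_exclude = 0.1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (n < 6) stop_param("leave-one-out prediction needs at least 6 subjects")
  pred <- numeric(n)
  fold_selected <- vector("list", n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    active <- stepwise_core(Xi, yi, alpha_enter, alpha_exclude)
    fold_selected[[i]] <- colnames(X)[active]
    if (length(active)) {
      fit <- fast_lm(Xi[, active, drop = FALSE], yi)
      pred[i] <- fit$beta[1] + sum(fit$beta[-1] * X[i, active])
    } else {
      pred[i] <- mean(yi)
    }
  }
  degenerate <- sd(pred) == 0 || sd(y) == 0
  r <- if (degenerate) 0 else cor(y, pred)
  structure(list(predicted = pred, actual = y, r = r,
                 fold_selected = fold_selected,
                 n_empty_folds = sum(lengths(fold_selected) == 0),
                 degenerate_r = degenerate),
            class = "loocv_result")
}

#' Permutation p-value for the LOOCV prediction correlation
#'
#' Permutes the response, re-runs the complete stepwise + leave-one-out
#' procedure, and compares permuted correlations against the observed one:
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (n_{perm} + 1)}.
#'
#' @inheritParams stepwise_regression
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional seed for the permutation stream.
#' @param observed Optional precomputed [loocv_predict()] result for the
#'   unpermuted response.
#' @return Numeric p-value with attributes `r_obs`, `null_r` (permuted
#'   correlations) and `n_perm`.
#' @export
permutation_pvalue <- function(X, y, n_perm = 100, seed = NULL,
                               alpha_enter = 0.05, alpha_exclude = 0.1,
                               observed = NULL) {
  check_count(n_perm, "n_perm", lower = 1L)
  if (sd(y) == 0) {
    stop_param("response is constant; the permutation null is degenerate")
  }
  if (is.null(observed)) {
    observed <- loocv_predict(X, y, alpha_enter, alpha_exclude)
  }
  r_obs <- observed$r
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      loocv_predict(X, sample(y), alpha_enter, alpha_exclude)$r
    }, numeric(1))
  })
  p <- (1 + sum(null_r >= r_obs)) / (n_perm + 1)
  structure(p, r_obs = r_obs, null_r = null_r, n_perm = n_perm)
}

#' Squared semi-partial correlation
#'
#' Increment in R-squared from adding `predictor` to a confound-only model
#' of `y`; equals the squared correlation between `y` and the
#' confound-residualized predictor. With no confounds it reduces to the
#' squared Pearson correlation.
#'
#' @param y Response vector.
#' @param predictor Predictor vector.
#' @param confounds Optional matrix/data frame of confounds.
#' @return Fraction in `[0, 1]`.
#' @export
semipartial_r2 <- function(y, predictor, confounds = NULL) {
  n <- length(y)
  if (is.null(confounds) || NCOL(confounds) == 0) {
    return(unname(cor(y, predictor)^2))
  }
  Z <- as.matrix(confounds)
  if (n <= ncol(Z) + 2) stop_param("too few observations for the confound set")
  if (qr(cbind(1, Z))$rank < ncol(Z) + 1) {
    stop_param("confound set is rank deficient")
  }
  r2_red <- fast_lm(Z, y)$r_squared
  r2_full <- fast_lm(cbind(Z, predictor), y)$r_squared
  max(0, r2_full - r2_red)
}
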