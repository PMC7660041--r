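#' Mixed-design ANOVA with partial eta squared
#'
#' Partitions sums of squares for one between-subject factor and up to two
#' within-subject factors (all interactions included) with subject-nested
#' error strata, and reports F, degrees of freedom, p and partial eta
#' squared \eqn{\eta_p^2 = SS_{effect} / (SS_{effect} + SS_{error})} with
#' the error term taken from the effect's own stratum. Degrees of freedom
#' are uncorrected by default; `gg = TRUE` applies a Greenhouse-Geisser
#' sphericity correction to within-subject effects.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param between Name of the between-subject factor (or `NULL`).
#' @param within Character vector of up to two within-subject factor names.
#' @param subject Name of the subject-id column.
#' @param gg Apply Greenhouse-Geisser correction to within effects.
#' @return Tibble with columns effect, df1, df2, ss, ss_error, F, p,
#'   partial_eta_sq (plus eps_gg when `gg`), and attribute `degenerate`
#'   when the response has zero variance.
#' @export
mixed_anova <- function(data, dv, between = NULL, within = NULL,
                        subject = "subject", gg = FALSE) {
  data <- as.data.frame(data)
  for (v in c(between, within, subject)) {
    if (!v %in% names(data)) stop_param("column '", v, "' not found")
    data[[v]] <- factor(data[[v]])
  }
  y <- data[[dv]]
  if (!is.numeric(y)) stop_param("dependent variable '", dv, "' must be numeric")

  # design completeness: one observation per subject x within-cell
  if (length(within)) {
    cells <- interaction(data[c(subject, within)], drop = FALSE)
    counts <- table(cells)
    if (any(counts != 1L)) {
      bad <- names(counts)[counts != 1L][1]
      stop_param("design is not complete/balanced at subject x condition cell '",
                 bad, "'")
    }
  }

  degenerate <- isTRUE(all.equal(var(y), 0)) || var(y) == 0
  fixed <- paste(c(between, within), collapse = " * ")
  if (length(within)) {
    err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "), "))")
    form <- stats::as.formula(paste(dv, "~", fixed, "+", err))
  } else {
    form <- stats::as.formula(paste(dv, "~", fixed))
  }
  fit <- stats::aov(form, data = data)
  smry <- summary(fit)

  rows <- list()
  strata <- if (length(within)) smry else list(`Error: Within` = smry)
  for (sname in names(strata)) {
    tab <- if (length(within)) strata[[sname]][[1]] else strata[[sname]][[1]]
    tab <- as.data.frame(tab)
    terms_here <- trimws(rownames(tab))
    res_row <- which(terms_here == "Residuals")
    ss_err <- if (length(res_row)) tab[res_row, "Sum Sq"] else NA_real_
    df_err <- if (length(res_row)) tab[res_row, "Df"] else NA_real_
    for (i in seq_len(nrow(tab))) {
      if (i %in% res_row) next
      eff <- gsub("\\s+", "", terms_here[i])
      ss <- tab[i, "Sum Sq"]
      df1 <- tab[i, "Df"]
      Fv <- if (degenerate) 0 else tab[i, "F value"]
      pv <- if (degenerate) NA_real_ else tab[i, "Pr(>F)"]
      peta <- if (degenerate || (ss + ss_err) == 0) 0 else ss / (ss + ss_err)
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = eff, df1 = df1, df2 = df_err, ss = ss, ss_error = ss_err,
        F = Fv, p = pv, partial_eta_sq = peta)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (gg && length(within)) out <- apply_gg(out, data, dv, within, subject)
  attr(out, "degenerate") <- degenerate
  out
}

# Greenhouse-Geisser epsilon per within-subject effect, estimated from the
# subject x cell score matrix collapsed onto that effect (pooled groups).
apply_gg <- function(tab, data, dv, within, subject) {
  eps <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    eff_terms <- strsplit(tab$effect[i], ":")[[1]]
    w <- intersect(eff_terms, within)
    if (!length(w)) next
    cell <- interaction(data[w], drop = TRUE)
    k <- nlevels(cell)
    if (k < 3) { eps[i] <- 1 } else {
      m <- tapply(data[[dv]], list(data[[subject]], cell), mean)
      S <- stats::cov(m)
      C <- diag(k) - 1 / k
      V <- C %*% S %*% C
      eps[i] <- sum(diag(V))^2 / ((k - 1) * sum(V * V))
    }
    tab$p[i] <- pf(tab$F[i], tab$df1[i] * eps[i], tab$df2[i] * eps[i],
                   lower.tail = FALSE)
  }
  tab$eps_gg <- eps
  tab
}

#' Bonferroni-adjusted post hoc t-tests
#'
#' Runs a paired or independent two-sided t-test for each contrast and
#' multiplies p-values by the number of contrasts (capped at 1).
#'
#' @param contrasts A list; each element a list with numeric vectors `x` and
#'   `y`, logical `paired`, and optionally `label`.
#' @return Tibble with label, t, df, p_raw, p_bonferroni.
#' @export
posthoc_ttests <- function(contrasts) {
  m <- length(contrasts)
  if (!m) stop_param("no contrasts supplied")
  rows <- lapply(seq_len(m), function(i) {
    ct <- contrasts[[i]]
    if (length(ct$x) < 2 || length(ct$y) < 2) {
      stop_param("contrast ", i, " needs at least 2 observations per cell")
    }
    if (identical(ct$x, ct$y) && isTRUE(ct$paired)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(ct$x) - 1),
                 p.value = 1)
    } else {
      tt <- t.test(ct$x, ct$y, paired = isTRUE(ct$paired), var.equal = TRUE)
    }
    tibble::tibble(label = ct$label %||% paste0("contrast", i),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   p_bonferroni = min(1, tt$p.value * m))
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
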