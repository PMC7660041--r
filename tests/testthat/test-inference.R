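test_that("mixed ANOVA matches the brute-force SS oracle exactly", {
  for (seed in c(9, 10, 11)) {
    d <- toy_222(seed)
    res <- mixed_anova(d, dv = "dv", between = "group", within = c("w1", "w2"))
    o <- ss_oracle_222(d)
    g <- function(e, col) res[[col]][res$effect == e]
    expect_equal(g("group", "ss"), o$group, tolerance = 1e-12)
    expect_equal(g("group", "ss_error"), o$sub_err, tolerance = 1e-12)
    expect_equal(g("w1", "ss"), o$w1, tolerance = 1e-12)
    expect_equal(g("group:w1", "ss"), o$`group:w1`, tolerance = 1e-12)
    expect_equal(g("w1", "ss_error"), o$sw1_err, tolerance = 1e-12)
    expect_equal(g("w2", "ss"), o$w2, tolerance = 1e-12)
    expect_equal(g("w1:w2", "ss"), o$`w1:w2`, tolerance = 1e-12)
    expect_equal(g("group:w1:w2", "ss"), o$`group:w1:w2`, tolerance = 1e-12)
    expect_equal(g("w1:w2", "ss_error"), o$resid, tolerance = 1e-12)
    # F from oracle: MS_effect / MS_error with the stratum dfs
    expect_equal(g("w1", "F"), (o$w1 / 1) / (o$sw1_err / 6), tolerance = 1e-12)
    expect_equal(g("group", "F"), (o$group / 1) / (o$sub_err / 6),
                 tolerance = 1e-12)
    # partial eta^2 definition
    expect_equal(g("group", "partial_eta_sq"),
                 o$group / (o$group + o$sub_err), tolerance = 1e-12)
    # SS conservation across strata
    ss_all <- sum(res$ss) + o$sub_err + o$sw1_err + o$sw2_err + o$resid
    expect_equal(ss_all, o$total, tolerance = 1e-9)
  }
})

test_that("between-only ANOVA F equals the squared pooled t statistic", {
  set.seed(12)
  d <- data.frame(subject = paste0("s", 1:20),
                  group = rep(c("g1", "g2"), each = 10),
                  dv = rnorm(20))
  res <- mixed_anova(d, dv = "dv", between = "group")
  tt <- t.test(dv ~ group, data = d, var.equal = TRUE)
  expect_equal(res$F[res$effect == "group"], unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("degenerate and malformed ANOVA inputs are handled", {
  d <- toy_222()
  d$dv <- 5
  res <- mixed_anova(d, dv = "dv", between = "group", within = c("w1", "w2"))
  expect_true(attr(res, "degenerate"))
  expect_true(all(res$F == 0))
  d2 <- toy_222()[-1, ]
  expect_error(mixed_anova(d2, dv = "dv", between = "group",
                           within = c("w1", "w2")), "subject x condition")
})

test_that("post hoc t-tests apply the Bonferroni cap and paired identity", {
  x <- c(1, 2, 3, 4)
  same <- posthoc_ttests(list(list(x = x, y = x, paired = TRUE)))
  expect_equal(same$t, 0)
  expect_equal(same$p_bonferroni, 1)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10) + 1
  one <- posthoc_ttests(list(list(x = a, y = b, paired = FALSE)))
  expect_equal(one$p_raw, one$p_bonferroni)
  # direct t-formula oracle, and m-fold correction
  three <- posthoc_ttests(list(
    list(x = a, y = b, paired = TRUE, label = "ab"),
    list(x = a, y = rev(a), paired = TRUE, label = "ar"),
    list(x = b, y = a, paired = FALSE, label = "ba")))
  dd <- a - b
  t_manual <- mean(dd) / (sd(dd) / sqrt(10))
  expect_equal(three$t[1], t_manual, tolerance = 1e-12)
  expect_equal(three$p_bonferroni[1], min(1, three$p_raw[1] * 3),
               tolerance = 1e-12)
})

test_that("zscore_table standardizes, is idempotent, errors on constants", {
  expect_equal(zscore_table(data.frame(a = c(1, 2, 3)))$a, c(-1, 0, 1))
  set.seed(4)
  tab <- data.frame(a = rnorm(20, 5, 3), b = runif(20), id = letters[1:20])
  z <- zscore_table(tab)
  expect_lt(abs(mean(z$a)), 1e-12)
  expect_equal(sd(z$a), 1, tolerance = 1e-12)
  expect_identical(z$id, tab$id)
  expect_equal(zscore_table(z)$a, z$a, tolerance = 1e-12)
  tab$c <- 2
  expect_error(zscore_table(tab), "'c'")
})

test_that("stepwise recovers an exact predictor and plants, with determinism", {
  set.seed(8)
  n <- 16
  X <- matrix(rnorm(n * 10), n, 10)
  colnames(X) <- paste0("v", 1:10)
  y <- X[, 4]
  m <- stepwise_regression(X, y)
  expect_identical(m$selected, "v4")
  expect_equal(unname(m$beta[["v4"]]), 1, tolerance = 1e-9)
  # two planted predictors recovered in most simulations
  hits <- 0
  for (b in 1:200) {
    set.seed(1000 + b)
    Xb <- matrix(rnorm(16 * 6), 16, 6)
    colnames(Xb) <- paste0("v", 1:6)
    yb <- 0.6 * Xb[, 1] + 0.4 * Xb[, 2] + rnorm(16, sd = 0.3)
    mb <- stepwise_regression(Xb, yb)
    if (all(c("v1", "v2") %in% mb$selected)) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.8)
  # collinear set errors
  Xc <- cbind(X[, 1:3], dup = X[, 1])
  expect_error(betalearn:::fast_lm(Xc, y), "collinear")
})

test_that("stepwise false-entry rate under the null tracks alpha_enter", {
  # with alpha_enter = 0.05 and 10 independent candidates the chance of
  # selecting at least one is roughly 1 - 0.95^10 ~ 0.40
  sel <- vapply(1:400, function(b) {
    set.seed(2000 + b)
    Xb <- matrix(rnorm(18 * 10), 18, 10)
    yb <- rnorm(18)
    length(betalearn:::stepwise_core(Xb, yb, 0.05, 0.1)) > 0
  }, logical(1))
  expect_gt(mean(sel), 0.25)
  expect_lt(mean(sel), 0.55)
})

test_that("LOOCV predicts perfectly for a deterministic relation", {
  set.seed(14)
  X <- matrix(rnorm(12 * 4), 12, 4)
  colnames(X) <- paste0("v", 1:4)
  y <- X[, 1]
  cv <- loocv_predict(X, y)
  expect_equal(cv$r, 1, tolerance = 1e-9)
  expect_equal(cv$predicted, y, tolerance = 1e-9)
  # boundary n = 6 runs and returns 6 predictions
  cv6 <- loocv_predict(X[1:6, ], y[1:6])
  expect_length(cv6$predicted, 6)
  expect_error(loocv_predict(X[1:5, ], y[1:5]), "at least 6")
})

test_that("LOOCV shows no optimism under independence", {
  # under the null the cross-validated correlation must not be positively
  # biased; it is in fact negatively biased (held-out mean predictions
  # anticorrelate with the held-out values), which the permutation test
  # absorbs because its null is built from the same procedure
  rs <- vapply(1:200, function(b) {
    set.seed(3000 + b)
    Xb <- matrix(rnorm(16 * 5), 16, 5)
    yb <- rnorm(16)
    loocv_predict(Xb, yb)$r
  }, numeric(1))
  expect_lt(mean(rs), 0.05)
  expect_gt(mean(rs), -1)
  expect_lt(mean(rs > 0.5), 0.1)
})

test_that("LOOCV is invariant to subject ordering", {
  set.seed(15)
  X <- matrix(rnorm(14 * 6), 14, 6)
  colnames(X) <- paste0("v", 1:6)
  y <- 0.7 * X[, 2] + rnorm(14, sd = 0.5)
  cv <- loocv_predict(X, y)
  perm <- sample(14)
  cvp <- loocv_predict(X[perm, ], y[perm])
  expect_equal(cvp$predicted, cv$predicted[perm], tolerance = 1e-9)
  expect_equal(cvp$r, cv$r, tolerance = 1e-9)
})

test_that("permutation p-value: bounds, determinism, degenerate input", {
  set.seed(16)
  X <- matrix(rnorm(14 * 3), 14, 3)
  colnames(X) <- paste0("v", 1:3)
  y <- X[, 1]
  p <- permutation_pvalue(X, y, n_perm = 100, seed = 5)
  expect_equal(as.numeric(p), 1 / 101, tolerance = 1e-12)
  p2 <- permutation_pvalue(X, y, n_perm = 100, seed = 5)
  expect_identical(as.numeric(p), as.numeric(p2))
  expect_error(permutation_pvalue(X, rep(1, 14)), "degenerate")
  expect_error(permutation_pvalue(X, y, n_perm = 0), "n_perm")
})

test_that("semi-partial r2: reductions and orthogonal predictors", {
  set.seed(17)
  y <- rnorm(30)
  x <- rnorm(30)
  Z <- matrix(rnorm(30 * 2), 30, 2)
  expect_equal(semipartial_r2(y, x), cor(y, x)^2, tolerance = 1e-12)
  # residualized-predictor identity
  rx <- resid(lm(x ~ Z))
  expect_equal(semipartial_r2(y, x, Z), cor(y, rx)^2, tolerance = 1e-9)
  # orthogonal constructed predictor
  x_orth <- resid(lm(rnorm(30) ~ y + Z))
  expect_lt(semipartial_r2(y, x_orth, Z), 1e-9)
  expect_error(semipartial_r2(y, x, cbind(Z, Z[, 1])), "rank deficient")
})

test_that("semi-partial r2 recovers a planted partial effect at n = 200", {
  set.seed(18)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  sr <- 0.4
  y_raw <- 0.5 * z1 - 0.3 * z2 + sr * scale(resid(lm(x ~ z1 + z2)))[, 1] +
    rnorm(n, sd = 0.6)
  got <- semipartial_r2(scale(y_raw)[, 1], x, cbind(z1, z2))
  expect_equal(got, sr^2 / var(y_raw), tolerance = 0.1, ignore_attr = TRUE)
})
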