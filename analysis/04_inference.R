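#!/usr/bin/env Rscript
# Stage 4: group statistics and the prediction analysis.
#
# Mixed-design ANOVA on the corrected endpoints (group x sequence type x
# time T0-T4) with partial eta squared, mixed ANOVAs on the beta measures
# (group x hemisphere x session), and the T4 prediction model in the
# patient group: Z-scored candidates, forward/backward stepwise selection
# (alphaEnter 0.05 / alphaExclude 0.1), leave-one-out cross-validation,
# a 100-iteration permutation test, and the squared semi-partial
# correlation of contralateral Post1 PMBR after regressing out prior
# performance, hand dominance and sleep.

suppressMessages({
  library(betalearn)
  library(dplyr)
  library(tidyr)
})

out <- "results"
covars <- read.csv(file.path(out, "covariates.csv"))
endpoints <- read.csv(file.path(out, "endpoints_repeated.csv"))
endpoints_rnd <- read.csv(file.path(out, "endpoints_random.csv"))
beta <- read.csv(file.path(out, "beta_measures.csv"))

long <- bind_rows(repeated = endpoints, random = endpoints_rnd,
                  .id = "sequence_type") |>
  pivot_longer(all_of(c("T0", "T1", "T2", "T3", "T4")),
               names_to = "time", values_to = "rmse") |>
  inner_join(covars[c("subject", "group")], by = "subject")
aov_perf <- mixed_anova(long, dv = "rmse", between = "group",
                        within = c("sequence_type", "time"))
write.csv(aov_perf, file.path(out, "anova_performance.csv"),
          row.names = FALSE)
cat("Performance ANOVA (group x sequence x time):\n")
print(as.data.frame(aov_perf), digits = 3)

bt <- beta |> inner_join(covars[c("subject", "group")], by = "subject")
aov_beta <- lapply(c(mrbd = "mrbd", pmbr = "pmbr",
                     baseline_beta = "baseline_beta"), function(m) {
  mixed_anova(bt, dv = m, between = "group",
              within = c("hemisphere", "session"))
})
write.csv(bind_rows(aov_beta, .id = "measure"),
          file.path(out, "anova_beta.csv"), row.names = FALSE)

cand <- candidate_table(endpoints, beta, covars, target = "T4")
pred <- predict_performance(cand, n_perm = 100, seed = 20260922)
print(pred)
jsonlite::write_json(
  list(selected = pred$selected, beta = as.list(pred$beta),
       r_squared = pred$r_squared, loocv_r = pred$r,
       p_permutation = pred$p_permutation,
       semipartial_r2_pmbr = pred$semipartial_r2),
  file.path(out, "prediction_t4.json"), auto_unbox = TRUE, digits = NA)
cat("Inference outputs written under", out, "\n")
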