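#!/usr/bin/env Rscript
# Stage 2: score tracking performance.
#
# Per-block RMSE between wrist and target, regression-corrected session
# endpoints T0-T5 (line over the first/last five blocks, evaluated at the
# session's first/final block), and the performance-change measures the
# learning analysis rests on.

suppressMessages({
  library(betalearn)
  library(dplyr)
})

out <- "results"
behavior <- read.csv(file.path(out, "behavior_samples.csv"))
covars <- read.csv(file.path(out, "covariates.csv"))

blocks <- table_to_tracking(behavior, fs = behavior_params()$sample_rate)
by_subject <- split(blocks, vapply(blocks, `[[`, "", "subject"))
timelines <- lapply(by_subject, performance_timeline)

endpoints <- endpoints_table(timelines, "repeated")
write.csv(endpoints, file.path(out, "endpoints_repeated.csv"),
          row.names = FALSE)
write.csv(endpoints_table(timelines, "random"),
          file.path(out, "endpoints_random.csv"), row.names = FALSE)

deltas <- bind_rows(lapply(timelines, function(tl) {
  tibble::tibble(subject = tl$subject, delta_performance(tl))
}))
write.csv(deltas, file.path(out, "deltas.csv"), row.names = FALSE)

pat <- covars$subject[covars$group == "patients"]
dp <- deltas |> filter(subject %in% pat, sequence_type == "repeated")
pct <- function(pair) mean(dp$delta_pct[dp$pair == pair])
cat(sprintf("Patients, repeated sequence (n = %d):\n", length(pat)))
cat(sprintf("  overall improvement T0->T2: %5.1f%%\n", pct("T0-T2")))
cat(sprintf("  offline boost      T1->T2: %5.1f%%\n", pct("T1-T2")))
cat(sprintf("  overnight change   T3->T4: %5.1f%% (negative = forgetting)\n",
            pct("T3-T4")))
cat(sprintf("  retention          T0->T4: %5.1f%%\n", pct("T0-T4")))
cat("Endpoint tables written under", out, "\n")
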