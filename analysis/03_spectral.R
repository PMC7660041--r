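#!/usr/bin/env Rscript
# Stage 3: movement-related beta power.
#
# Morlet wavelet power (7 cycles) on the cue-aligned epochs, rescaled to
# percent change from the pre-movement baseline, then pooled over the
# sensorimotor electrodes: MRBD over 1-2 s x 15-30 Hz, PMBR over
# 6-7 s x 10-25 Hz, and absolute resting beta power in the baseline
# window, per hemisphere (contralateral/ipsilateral to the trained hand)
# and EEG session. Epochs are re-materialized deterministically from the
# stage-1 seed; one session is also read back from the exported EDF to
# exercise the file path.

suppressMessages({
  library(betalearn)
  library(dplyr)
  library(tidyr)
})

out <- "results"
seed <- 20260921
spec <- cohort_spec(n_patients = 16, n_controls = 20, seed = seed,
                    n_trials = 24, eeg_fs = 100, epoch_window = c(-1, 7.5),
                    channels = montage_compact())
cohort <- generate_cohort(spec)

# EDF round trip for one session, then epoching with artifact rejection
rec <- read_eeg(file.path(out, "p01_Post1.edf"))
ep_file <- epoch_and_reject(rec, window = spec$epoch_window, threshold = Inf)
cat("EDF check: p01/Post1 re-read,", length(ep_file$retained),
    "trials epoched from file.\n")

beta <- cohort_beta_measures(cohort)
write.csv(beta, file.path(out, "beta_measures.csv"), row.names = FALSE)

summ <- beta |>
  inner_join(cohort$covariates[c("subject", "group")], by = "subject") |>
  group_by(group, session, hemisphere) |>
  summarise(mrbd = mean(mrbd), pmbr = mean(pmbr), .groups = "drop")
cat("Group-mean beta measures (percent change from baseline):\n")
print(as.data.frame(summ), digits = 3)
cat("Beta measures written under", out, "\n")
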