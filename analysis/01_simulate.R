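#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 16 chronic stroke patients and 20 age-matched controls train on the
# continuous tracking task (40 blocks), are retested after ~45-60 min
# (5 blocks) and after 24 h (10 blocks), and perform the cued wrist
# flexion/extension task during three EEG sessions (Pre, Post1, Post2).
# A known association between contralateral post-training PMBR and the
# 24-h retention endpoint (T4) is planted so later stages can be checked
# against ground truth. EEG here is generated at a reduced scale
# (24 trials, 16-channel montage, 100 Hz) so the whole workflow runs in
# minutes; the generator supports the full 120-trial/64-channel/300-Hz
# setting through the same interface.

suppressMessages({
  library(betalearn)
  library(dplyr)
})

seed <- 20260921
out <- "results"
dir.create(out, showWarnings = FALSE)

spec <- cohort_spec(n_patients = 16, n_controls = 20, seed = seed,
                    n_trials = 24, eeg_fs = 100, epoch_window = c(-1, 7.5),
                    channels = montage_compact())
cohort <- generate_cohort(spec)

write.csv(cohort$covariates, file.path(out, "covariates.csv"),
          row.names = FALSE)
behavior <- bind_rows(lapply(cohort$behavior, tracking_to_table))
write.csv(behavior, file.path(out, "behavior_samples.csv"), row.names = FALSE)
write.csv(cohort$osc, file.path(out, "ground_truth_oscillations.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       latents = cohort$ground_truth$latents,
       planted = unclass(cohort$ground_truth$planted)),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

# one EEG session exported as EDF + events, demonstrating the on-disk format
ep <- subject_epochs(cohort, "p01", "Post1")
flat <- matrix(aperm(ep$data, c(2, 3, 1)), nrow = dim(ep$data)[2])
onsets <- as.integer((seq_len(dim(ep$data)[1]) - 1) * dim(ep$data)[3] +
                       round(-spec$epoch_window[1] * spec$eeg_fs) + 1)
rec <- eeg_recording(flat, ep$channels, ep$fs,
                     tibble::tibble(onset_sample = onsets,
                                    condition = rep_len(c("flexion", "extension"),
                                                        length(onsets))))
write_edf(rec, file.path(out, "p01_Post1.edf"))

cat("Simulated", nrow(cohort$covariates), "subjects;",
    nrow(behavior), "behavioural samples.\n")
cat("Planted effect:", cohort$ground_truth$planted$predictor, "->",
    cohort$ground_truth$planted$target, "slope",
    cohort$ground_truth$planted$slope, "\n")
cat("Tables written under", out, "\n")
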