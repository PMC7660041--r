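# betalearn

Analysis pipelines linking sensorimotor-cortex beta oscillations
(15–30 Hz) to motor skill learning, for studies of the kind run in
post-stroke motor rehabilitation research: patients and controls train on
a continuous wrist-tracking task, are retested after ~1 h and after 24 h,
and perform a simple cued wrist movement during EEG before and after
training. The package answers three questions end to end:

1. **How much did people learn?** Tracking performance is scored per block
   by root-mean-square error (RMSE) between wrist and target angle; each
   session's start/end performance is estimated by OLS lines over its
   first/last five blocks (endpoints T0–T5), correcting for temporary
   effects such as fatigue.
2. **How did beta oscillations change?** EEG epochs around each movement
   cue are decomposed with 7-cycle Morlet wavelets, rescaled to percent
   change from the pre-movement baseline (−1..0 s), and summarized per
   hemisphere as movement-related beta desynchronization (MRBD, 1–2 s ×
   15–30 Hz), post-movement beta rebound (PMBR, 6–7 s × 10–25 Hz) and
   absolute resting beta power, over fixed sensorimotor electrode pools.
3. **Do beta measures predict future performance?** All variables are
   Z-scored, a forward/backward stepwise regression (entry p < 0.05,
   exclusion p > 0.1) is built for a future endpoint (e.g. T4, 24 h after
   training), validated by leave-one-out cross-validation with the full
   selection re-run in every fold, and tested against a 100-iteration
   permutation null; the contribution of one predictor over confounds is
   quantified by the squared semi-partial correlation.

Because raw recordings of such studies are typically not shareable, the
package includes a first-class synthetic-cohort generator
(`generate_cohort()`): behavioural learning curves with sequence-specific
learning, fatigue, offline boost and overnight forgetting; event-related
oscillatory EEG (1/f background + band-limited beta sources with
configurable MRBD/PMBR envelopes, per subject/session/hemisphere); and a
*planted*, confounded association between contralateral post-training
PMBR and the 24-h endpoint, so that the whole chain can be verified
against known ground truth. See the methods vignette
(`vignettes/beta-learning-pipeline.Rmd`) for the models and every default.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → behaviour → spectral → inference → calibration), writing its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_behavior.R
Rscript analysis/03_spectral.R
Rscript analysis/04_inference.R
Rscript analysis/05_calibration.R
```

Stage 2 prints the behavioural learning effects for the simulated patient
group (repeated sequence, n = 16):

```
Patients, repeated sequence (n = 16):
  overall improvement T0->T2:  18.0%
  offline boost      T1->T2:  14.4%
  overnight change   T3->T4:  -9.6% (negative = forgetting)
  retention          T0->T4:   8.0%
```

i.e. most of the apparent improvement only surfaces at the first retest
(fatigue masks learning at the end of training), followed by overnight
forgetting — the qualitative signature this task is known for. Stage 4
prints the prediction analysis in the patients:

```
Endpoint prediction (n = 16)
Stepwise linear model (alphaEnter 0.05, alphaExclude 0.1)
  T3                           beta =   0.911  t =  29.58  p = 2.82e-10
  mrbd_ipsilateral_Pre         beta =   0.250  t =   7.56  p = 3.484e-05
  pmbr_contralateral_Post1     beta =   0.148  t =   5.02  p = 0.0007213
  pmbr_ipsilateral_Post1       beta =   0.148  t =   4.68  p = 0.001152
  sleep_quantity               beta =  -0.098  t =  -3.28  p = 0.009546
  grip_strength                beta =  -0.103  t =  -3.23  p = 0.0104
  R^2 = 0.993 on 16 obs
  LOOCV r(actual, predicted) = 0.895, permutation p = 0.0099 (100 perms)
  semi-partial r^2 of pmbr_contralateral_Post1 = 0.017
```

The model finds prior performance (T3), sleep with a negative coefficient,
and contralateral Post1 PMBR with a positive coefficient — higher
post-training rebound goes with worse (higher-RMSE) performance 24 h
later, i.e. smaller PMBR predicts better retention, exactly the structure
the generator planted. The permutation p-value sits at its minimum
attainable value (1/101). Stepwise selection at n = 16 is noisy by
nature: some spurious candidates ride along in any single cohort, and the
planted predictor itself is recovered in roughly three quarters of
cohorts — stage 5 quantifies this:

```
Null rejection rate at p < 0.05: 0.060 (50 repeats)
Planted PMBR predictor selected in 76% of cohorts;
coefficient sign correct in 100% of selections.
```

Equivalent single calls: `run_pipeline(pipeline_config(...))` runs the
whole chain in memory and writes a JSON summary whose tables carry a
configuration hash (`join_checked()` refuses to join tables from different
runs).

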