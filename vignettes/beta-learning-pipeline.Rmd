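---
title: "Beta oscillations and motor skill learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta oscillations and motor skill learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(betalearn)
```

betalearn implements a complete analysis chain for studies that relate
sensorimotor-cortex beta oscillations (15–30 Hz) to short-term motor skill
learning: a continuous wrist-tracking task scored by root-mean-square error
(RMSE), event-related EEG during a simple cued wrist movement decomposed
with Morlet wavelets, and group/prediction statistics. Because raw clinical
recordings of this kind are rarely shareable, the package ships a
synthetic-cohort generator with known ground truth; every downstream stage
is exercised and validated against it.

## The behavioural model

Subjects track a target moving through a fixed arc; performance in block
$b$ is the RMSE between wrist and target angle. The generator's mean curve
is

$$m(b) = \mathrm{initial} - A_s\,(1 - e^{-\rho b}) +
  \phi \max(0, b - b_0),$$

with cumulative block number $b$ (training 1–40, retest1 41–45, retest2
46–55), $A_s = \mathrm{amplitude}\,(1 + \mathrm{gain})$ for the repeated
sequence and $A_s = \mathrm{amplitude}$ for random sequences, learning rate
$\rho$ and a linear fatigue term $\phi$ active after block $b_0$ during
training only. Retest sessions are shifted multiplicatively: an offline
boost (both sequences) and, overnight, forgetting (repeated sequence only).
An exponential-plus-fatigue form was chosen because published learning
curves of this task show saturating improvement with a late-training
decrement; no specific functional form is established, so the curve is a
package design choice, exposed in `behavior_params()`.

Defaults (degrees, per block): initial RMSE 10, patient amplitude 0.6
(controls 1.2 — about half the patient improvement, mirroring the reduced
learning observed in chronic stroke), rate 0.08, sequence gain 0.5, fatigue
0.04/block from block 30, boost 7%, forgetting 10%, block-level noise SD
0.3. These reproduce the qualitative pattern the task is known for: no net
improvement at the end of training (fatigue masks learning), a boost at the
45–60 min retest, ~11% overall improvement of the repeated sequence at T2,
and ~10% overnight forgetting.

The simulator writes wrist = target + error, where the error process is a
smooth AR(1) trace rescaled so its RMS equals the (noise-perturbed) mean
curve *exactly*; with `noise_sd = 0` the scored block RMSE therefore equals
$m(b)$ to machine precision, which the unit tests exploit.

### Scoring

`compute_rmse()` is the plain quadratic mean of instantaneous angular
error. The paper-style endpoint correction (`corrected_endpoints()`) fits
an OLS line over the first and last five blocks of each session and
evaluates it at the session's first and final block, yielding T0/T1
(training), T2/T3 (retest1, one line for both since it has exactly five
blocks) and T4/T5 (retest2). The evaluation points are configurable — the
procedure is only specified as "corrected for temporary effects" in the
source literature, so evaluating the fits at the session boundaries is our
documented choice. Sequences are fitted separately (a pooled option exists
in the scoring code path by filtering the RMSE table first). Percentage
change measures use the subject's repeated-sequence T0 as denominator.

## The EEG model

Each trial of the simple motor task is simulated as

$$x_c(t) = \sum_{h \in \{L,R\}} w_{hc}\, a_h(t)\, s_h(t) + \eta_c(t),$$

where $s_h$ is a stationary beta source for hemisphere $h$, $a_h(t)$ its
amplitude envelope, $w_{hc}$ a topography peaked over the sensorimotor
electrodes (C3/CP3/C1/CP1 and mirrored), and $\eta_c$ spectrally shaped
$1/f$ Gaussian noise, independent per channel. The envelope is 1 at
baseline, $1 + \mathrm{mrbd\_depth}$ inside the movement window
(default 0.5–4.5 s) and $1 + \mathrm{pmbr\_gain}$ inside the rebound window
(default 5.5–8 s), with raised-cosine ramps (0.25 s) to limit spectral
splatter. An amplitude scale of $s$ yields a band power change of
$s^2 - 1$, the closed form every calibration check uses.

The default source is band-limited noise spanning 10–30 Hz
(`beta_bw = 20`) rather than a pure sinusoid: PMBR is known to occupy
lower beta frequencies (10–25 Hz) than MRBD (15–30 Hz), and a band-wide
source gives every analysis bin genuine signal so that band-averaged
percent change reflects the injected scaling without dilution.
`beta_bw = 0` selects a pure 20 Hz sinusoid, used in closed-form tests.
Default amplitudes put in-band beta power well above the $1/f$ background
(a high-SNR regime): with noise the band-averaged MRBD of an injected
amplitude halving reads about $-72\%$ instead of the ideal $-75\%$. Real
recordings have lower SNR and correspondingly stronger attenuation — a
limitation of what passing calibrations at these defaults can claim about
real data.

**Degenerate inputs.** For a noiseless narrowband input, frequency bins
carrying essentially no power have baselines at the level of numerical
leakage, and percent change there is meaningless. This cannot occur with
any nonzero background; closed-form checks on sinusoids therefore evaluate
at the carrier frequency or within the band that carries signal.

### Spectral pipeline

`preprocess()` average-references, band-passes 5–100 Hz (zero-phase
4th-order Butterworth), notches 50 Hz (zero-phase biquad, Q = 30; no
filter types are prescribed in the source literature, these are standard
choices) and resamples to 300 Hz, remapping event onsets.
`epoch_and_reject()` cuts −1..9 s epochs around each cue and drops trials
whose peak-to-peak amplitude exceeds 150 µV (configurable; the exclusion
criteria are otherwise unspecified).

`morlet_power()` convolves with 7-cycle complex Morlet wavelets
($\sigma_t = 7 / 2\pi f$), unit-energy normalized (all reported measures
are ratios, so the absolute scale convention is internal), kernels
truncated at $4\sigma_t$, epochs padded by 1 s and cropped after
convolution. Padding uses point-symmetric (odd) reflection about the end
samples rather than a plain mirror: a plain mirror leaves a slope
discontinuity at the pad boundary whose broadband splatter measurably
inflates baseline power at low-power frequency bins (the widest kernels
reach the boundary from inside the baseline window); odd reflection is
continuous in value and slope and reduces the noiseless calibration error
of the band-averaged MRBD by an order of magnitude. The default grid is 5–45 Hz at 0.1 Hz; `coarse_freqs()`
(0.5 Hz) and `measure_freqs()` (10–30 Hz at 2.5 Hz) support fast runs.
Because the beta measures only need window means, `time_points` evaluates
the transform at a 0.1 s raster inside the analysis windows via
truncated-kernel inner products; at the sampled instants this equals the
full transform to machine precision (both paths share the truncation), and
a unit test enforces that equality.

`baseline_rescale()` converts to percent change relative to the
pre-movement baseline. The nominal baseline is −1..0 s; the default window
is −0.9..0 s because the first 0.1 s abuts the epoch edge where padded
convolution is least reliable.

`extract_beta_measures()` averages jointly over electrode pool × band ×
window: MRBD over 1–2 s × 15–30 Hz (pools C3/CP3/CP1 and C4/CP4/CP2),
PMBR over 6–7 s × 10–25 Hz (pools C1/C3/CP3 and C2/C4/CP4), resting beta
power as absolute power in the baseline window over the union of the two
pools per hemisphere (the exact resting-pool membership is ambiguous in
the source literature; the union is our documented default, configurable
in `electrode_pools()`). Whether pool and time–frequency averaging is
joint or sequential only changes pool weighting; the joint mean is used.
Hemispheres are labelled contralateral/ipsilateral to the trained hand via
the generator's mirror flag; flipping the flag exactly swaps the labels.

## Inference

`mixed_anova()` partitions sums of squares for one between-subject factor
and up to two within-subject factors with subject-nested error strata
(built on `aov()`'s `Error()` mechanism; a brute-force SS decomposition
serves as an independent oracle in the tests) and reports partial
$\eta^2 = SS_e/(SS_e + SS_{err})$ within each effect's own stratum.
Degrees of freedom are uncorrected by default, matching how such designs
are usually reported; `gg = TRUE` applies Greenhouse–Geisser correction.
`posthoc_ttests()` Bonferroni-adjusts by multiplying raw p-values by the
number of contrasts, capped at 1.

The prediction analysis Z-scores all variables, then runs forward/backward
stepwise selection with entry p < 0.05 and exclusion p > 0.1. The entry
statistic is the partial t-test of each candidate given the current model;
ties break by column order so runs are deterministic. Candidates for the
T4 model: T0–T3, the six beta measures at Pre and at Post1 (both
hemispheres), age, affected-hand dominance, sleep quantity and quality,
grip strength, NHPT and SART — the full supplementary candidate list is
not available, so the set is configuration-driven in `candidate_table()`.

`loocv_predict()` reruns the *entire* selection within every
leave-one-out fold; folds that select nothing predict the fold-training
mean (a logged contract, not an error). Predictive strength is the
correlation between actual and predicted values. One consequence worth
knowing: under the null, held-out mean predictions are anticorrelated with
the held-out values, so the null distribution of the LOOCV correlation is
negatively biased. This does not affect the permutation test
(`permutation_pvalue()`, response permuted, predictors fixed, add-one
convention $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$, minimum
$1/101$ at 100 permutations) because its null is built from the same
procedure; the acceptance suite verifies a ~5% rejection rate under the
global null. The permutation statistic is the correlation itself, the
quantity the analysis reports. `semipartial_r2()` is the R² increment of
adding one predictor to a confound-only model.

## The planted prediction effect

`planted_effect()` wires a known association into the cohort: the target
endpoint's session mean is shifted by

$$\Delta_i = \sigma_T \left( \beta_p z_i^{\mathrm{PMBR}} +
 \beta_a a_i + \beta_s z_i^{\mathrm{sleep}} + \beta_h z_i^{\mathrm{hand}} +
 \sigma_\varepsilon \varepsilon_i \right),$$

with the subject's standardized contralateral-Post1 PMBR deviation
$z^{\mathrm{PMBR}}$, latent learning ability $a_i$ (also visible in the
retest1 endpoints T2/T3), sleep quantity and affected-hand dominance.
Defaults: $\beta_p = 0.3$, $\beta_a = 0.85$, $\beta_s = -0.16$,
$\beta_h = 0.13$, $\sigma_\varepsilon = 0.2$, $\sigma_T = 2.0$°. The
confound slopes are the magnitudes reported for this analysis in the
motivating study; the residual is set so that the *latent* model is
slightly cleaner than the *measured* one (the reported model explained 82%
of endpoint variance with a strong partial effect of PMBR, t ≈ 4.8 — and
measurement noise in both EEG and behaviour attenuates whatever is
planted). $\sigma_T = 2$° matches the between-subject endpoint spread
implied by published group-level error bars. Between-subject oscillation
spreads: PMBR gain 0.25 ± 0.10, MRBD depth −0.35 ± 0.10, log-normal
baseline amplitude (σ = 0.2), stable per subject.

## Study sizes

The Monte-Carlo studies are sized for a single CPU:

* Null calibration: 200 repeats × (1 + 100 permutations) leave-one-out
  runs at n = 16 with 15 candidates.
* Planted-effect recovery: 200 cohorts of 16 patients; EEG at 48
  trials/session, 80 Hz, −1..7.5 s epochs, pooled sensorimotor channels
  only, 10–30 Hz measure grid at 2.5 Hz. At these sizes the beta-measure
  reliability (correlation between estimated and injected PMBR deviations)
  is ≈ 0.95, so recovery is dominated by the latent design, not by
  measurement error.
* The demonstration pipeline in `analysis/` uses 36 subjects with
  24-trial, 16-channel, 100 Hz EEG sessions.

Sampling rates below the recording standard are legitimate here because
every analysis band lies far below Nyquist even at 80 Hz; the generator
refuses rates that violate Nyquist for the configured source.

## What the synthetic data does and does not emulate

Emulated: block-level learning dynamics with sequence specificity, fatigue,
offline boost and overnight forgetting; event-related beta dynamics with
realistic window structure, per-subject/hemisphere/session variability and
hemispheric lateralization; 1/f background; covariate distributions typical
of a chronic-stroke cohort; a planted, confounded prediction structure.

Not emulated: volume conduction and realistic topography beyond fixed
channel weights; artifacts other than optional amplitude outliers (no eye
blinks, EMG); non-stationary background; per-subject beta peak frequencies;
floor/ceiling effects in tracking. Passing calibration at the simulator's
high-SNR defaults therefore demonstrates correctness of the estimators, not
robustness to every pathology of clinical EEG.

## Known limitations

* The stepwise + LOOCV procedure inherits the instabilities of stepwise
  selection at n = 16; the package reports fold-wise selections so users
  can see them.
* Percent-change measures are undefined where baseline power is zero;
  the pipeline raises an error rather than returning infinities.
* The EDF writer covers the subset of the format the pipeline needs
  (16-bit, one-second records, uniform rate).
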