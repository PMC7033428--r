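---
title: "Predicting reaction-time delays from pre-cue EEG bandpower: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reaction-time delays from pre-cue EEG bandpower}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An operator performing a monitoring task (the motivating setting is a
pilot in a flight simulator) responds to occasional visual cues with a
button press. The response delay — the time between cue onset and the
press — fluctuates from trial to trial, and sustained increases are a
safety concern. `eegrt` implements a pipeline that predicts each trial's
delay from the EEG recorded *immediately before* the cue appears, so the
prediction reflects the operator's neural state at the moment a reaction
becomes necessary, not the reaction itself.

The pipeline has five stages:

1. **Epoching.** For every cue, the pre-cue window (default 0.5 s = 64
   samples at 128 Hz) is cut from the continuous 14-channel recording.
   Windows are half-open and end strictly before the cue sample: the cue
   time is mapped to sample index `floor(t * fs)` and the epoch is
   `[idx - 64, idx)`. Flooring (rather than rounding) guarantees that no
   sample recorded at or after the physical cue can leak into the
   predictor window. Trials whose window would precede the start of the
   recording are dropped and reported.
2. **Band decomposition.** Each window and channel is decomposed into ten
   classical frequency bands (Delta 1–4, Theta 4–8, Alpha 8–12, three
   Beta subdivisions 12–24, High Beta 24–28, Gamma 32–36 and 36–40, and a
   Broad 8–30 Hz sensorimotor range) by zero-padded FFT filtering.
3. **Features.** Each band-limited signal is summarized by its
   log-variance (`logvar`), giving 14 × 10 = 140 bandpower features per
   trial. Features are z-scored with statistics estimated from training
   trials only.
4. **Regression.** Four regressors — LASSO, LASSO solved along the same
   path (`lasso_lars`), RBF kernel ridge, and RBF support vector
   regression — are tuned by exhaustive grid search under 3-fold
   cross-validation minimizing MAE, then evaluated on 11 random 75/25
   train/test splits. A shuffled-label SVR control quantifies what "no
   EEG information" looks like under the identical protocol.
5. **Statistics.** Per-session delay summaries with a Huber-robust linear
   trend over time-in-session, one-way ANOVA across the algorithms'
   absolute errors, and pairwise t-tests.

Because the original recordings are not publicly distributable, the
package ships a synthetic-session generator whose ground truth (which
channel/band powers drive the delay, and by how much) is known, so every
stage — including the full protocol's ability to recover a planted
coupling — is testable end to end.

## Zero-padded FFT bandpass filtering

A 64-sample window gives 2 Hz Fourier bins, too coarse for 4 Hz wide
bands. The implementation therefore:

1. subtracts the window mean;
2. appends 192 zeros (64 → 256 samples, bin spacing 0.5 Hz);
3. takes the FFT and zeroes every bin whose frequency magnitude lies
   outside the half-open band `[f_low, f_high)`, masking negative
   frequencies symmetrically so the inverse transform is real, with the
   DC bin always zeroed;
4. inverse-transforms and keeps only the first 64 samples, so features
   never describe the padding.

Numerical choices worth stating:

* **Half-open band edges.** The bands share edges (4, 8, 12, … Hz); the
  `[low, high)` convention ensures a bin that falls exactly on a shared
  edge is counted in exactly one band. The 28–32 Hz gap between High
  Beta and Gamma 1 is intentional and preserved. Whether shared-edge
  bins should instead be double-counted is an open convention; the
  half-open choice is the one that keeps disjoint-band reconstructions
  exactly additive (a tested invariant).
* **Mean removal.** Zero padding a segment with non-zero mean creates a
  spurious low-frequency component. Since no band extends below 1 Hz,
  demeaning plus a zeroed DC bin discards that artifact without touching
  any band content.
* **Zeros appended at the end only**, matching the layout of the
  brute-force oracle used in the tests, so correctness is checked
  convention-for-convention.
* **No taper.** The rectangular 64-sample window leaks: an in-band tone
  at the band centre keeps ≈ 87 % of its variance, a tone 1 Hz from a
  band edge only ≈ 70–80 %, and reconstructing a pure in-band tone shows
  edge ringing up to ≈ 0.44 of the unit amplitude (median deviation
  < 0.1). These numbers are frozen in the tests from an independent
  brute-force DFT-projection oracle (direct summation per retained
  coefficient); they are properties of the method, not defects of the
  implementation. Out-of-band tones ≥ 2 bins away retain < 5 % variance.

## logvar features and standardization

A bandpass-filtered signal has near-zero mean, so its variance measures
band power; the natural log brings the heavy-tailed power distribution
close to normal. Variance uses the population (1/N) convention — the
choice is irrelevant after z-scoring but is fixed so fixtures are
reproducible. Columns are ordered channel-major (all ten bands of AF3,
then F7, …) and labelled `CHANNEL_Band`, e.g. `O1_Alpha`; the labels
drive the selected-feature reports.

Standardization statistics (mean and population sd per column) are
estimated from the training rows of each split only and applied
unchanged to the test rows. The alternative — scaling on all trials
before splitting — leaks test-set information into training; the
leak-free reading is implemented. A zero-variance training column is an
error naming the offending channel/band, since it indicates a dead
channel or an all-zero band.

## Evaluation protocol

For each of 11 repetitions (seeded `base_seed + r`), trials are
partitioned at random into 75 % training / 25 % test, with the training
size defined as round-half-away-from-zero of 0.75 n (n = 48 gives
36/12). Inside each repetition every model is tuned by exhaustive grid
search: each grid point is scored by the mean MAE over a 3-fold
cross-validation of the training rows, the lowest mean wins, and ties go
to the first point in grid order. The winning settings are refit on all
training rows and evaluated on the held-out trials.

The per-subject score is

```
MAE_s = (1/11) * sum_r [ mean_m |yhat_rm - y_rm| ]
```

— the unweighted mean of per-repetition mean absolute errors, *not* the
pooled mean over all errors (the two differ when repetitions have
unequal test sizes; a test asserts the distinction). Reported alongside
are the sd and the maximum of the pooled absolute errors.

Default grids (all overridable per `model_spec`): LASSO λ over 7
log-spaced values in 1e-4…10; kernel ridge α ∈ 1e-3…100, γ ∈ 1e-4…10 (6
each); SVR C ∈ 1e-2…1e3, γ ∈ 1e-4…10, ε ∈ {0.01, 0.05, 0.1} s. These are
plausible defaults chosen for this package, not a reconstruction of any
particular prior study's grids.

Design choices in this module:

* **SVR feature selection.** The SVR variants rank columns once per
  repetition by absolute Pearson correlation with the training targets
  and tune the count k ∈ {5, 10, 20, 40, 140} inside the same grid. This
  is the simplest rank-and-select scheme consistent with an "initial
  feature ranking and selection" step; the ranking function is a single
  internal routine and can be swapped.
* **Both LASSO entries use glmnet's coordinate descent.** LASSO and its
  least-angle-regression variant solve the same convex problem; no LARS
  solver is available in the dependency set, and re-deriving solvers is
  explicitly out of scope, so the two specs coincide here apart from
  their grids.
* **Kernel ridge** is the closed-form dual solve
  `(K + αI) a = y - ȳ` with an RBF kernel, checked in the tests against a
  directly constructed oracle.
* **Degenerate SVR fits.** When the ε tube is wide enough to contain
  every training target the SVR has no support vectors; such a model
  degenerates, by definition of the ε-insensitive loss, to predicting
  the training mean, and is handled that way rather than erroring — the
  situation arises legitimately in the null (no-coupling) setting where
  delay spread ≈ ε.
* **Shuffled control.** `shuffled_svr_rbf` permutes the *training*
  targets (seeded per repetition) before tuning and fitting; test
  targets stay true. Its MAE is what one earns by predicting without
  EEG information — empirically close to predicting the training mean.

## Robust trend and group statistics

The delay-vs-time trend uses a hand-implemented iteratively reweighted
least squares with Huber's T criterion: residual scale MAD/0.6745,
weight 1 inside `|r|/scale ≤ c` and `c/(|r|/scale)` outside, c = 1.345
(the canonical 95 % Gaussian-efficiency constant), iterating from OLS
until the largest coefficient change < 1e-8 (max 50 iterations,
non-convergence is an error with the change trace). The slope p-value
uses the asymptotic normal statistic slope/se from the final weighted
fit; the reference distribution is a documented package choice. Tests
cross-check against `MASS::rlm` and verify the c → ∞ limit equals OLS.
Note that with Gaussian noise roughly 18 % of residuals exceed the Huber
threshold, so the robust slope differs from OLS at the order of a
fraction of a standard error even on outlier-free data; exact OLS
agreement holds (and is tested) when all residuals stay inside the
quadratic region.

ANOVA is the classical equal-variance one-way F on pooled absolute
errors with algorithms as groups (concatenating all repetitions' errors;
per-repetition means would be the alternative pooling). Pairwise t-tests
default to unpaired Welch — group sizes can differ when trials are
dropped — with a paired mode for matched designs and an optional
Holm/Bonferroni correction that is off by default (raw p-values are
reported). A paired comparison whose differences are all zero is
reported as p = 1 by convention.

## The synthetic-session generator

The generator emulates the study conditions the analysis assumes:

* **Cue schedule.** Inter-cue intervals ~ N(150 s, 60 s), resampled
  below a 10 s floor (back-to-back cues are physically implausible; the
  normal has non-negligible mass near zero). Scheduling stops one window
  plus a 5 s margin before session end so the slowest response still
  falls inside the recording. A configuration whose truncation would
  discard more than half the draws is rejected as degenerate. Over 200
  seeds a 7200 s session averages ≈ 47 events (the 10 s floor raises the
  mean gap slightly above 150 s).
* **EEG.** Each channel is a sum over the ten bands of a sinusoid at the
  band's mid-frequency. Its amplitude is 2 µV outside pre-cue windows
  and, inside trial i's window, a per-trial log-normal draw (median
  5 µV, sdlog 0.6). Log-normal amplitudes make the logvar features
  approximately normal, which is the transform's rationale. Added to
  this is 1/f (pink) broadband noise at 4 µV RMS, plus an optional 50 Hz
  mains tone that is off by default (acquisition hardware notch-filters
  mains). The amplitude parameters were fixed once, at design time, so
  that the planted per-trial log-variance is recovered from the
  synthesized signal with correlation ≈ 0.97 — strong enough that
  recovery failures indicate pipeline defects, weak enough that the
  regression problem is not trivial.
* **Delays.** `delay_i = max(0.25, 0.55 + Σ_j coef_j · logvar_ij + ε_i)`
  with ε ~ N(0, 0.05 s); the coupling map (feature → seconds per logvar
  unit) is empty by default and set to `c(O1_Alpha = 0.2)` in the
  recovery scenario. Responses are emitted as `cue + delay`, so the
  event table has the same shape as a real recording's markers and
  delays are recomputed from files identically for real and synthetic
  data.

What the generator does *not* emulate: eye-blink/EMG artifacts, volume
conduction (each channel is independent), non-stationary background
rhythms, and any physiological relation between bands. Passing the
recovery tests therefore shows the *pipeline* is correct and sensitive,
not that real EEG carries the planted effect; conclusions about real
data require real recordings.

Whether a cue may overlap the previous trial's response is not
constrained by the emulated protocol description; the generator forbids
it via the 10 s minimum gap without claiming the original experiment
did.

## Problem sizes used in the shipped tests

The test suite exercises the full-length configuration where the
property under test demands it (the 2-hour schedule statistics over 200
seeds; one full session with a planted coupling evaluated under the
default SVR grids; twenty full null sessions under a compact SVR grid
for the null-equivalence calibration, where grid breadth is not the
property being tested) and ten-minute sessions (~14 trials) for
pipeline plumbing checks. Statistical calibration tests use 500
simulations (t-test size) and 50 simulated subjects (drift recovery).

## Known limitations

* EDF support covers continuous recordings with one common sampling rate
  and whole-second durations; use CSV otherwise.
* No spatial filtering, re-referencing, wavelet decomposition, or
  alternative feature families (entropy, coherence): logvar bandpower is
  the single descriptor by design.
* The evaluation protocol assumes trials are exchangeable; it does not
  implement blocked or chronological splits, so temporal drift in
  features can inflate apparent performance on real data.
* `lasso` and `lasso_lars` coincide (same solver) in this
  implementation; they are kept as separate specs for protocol parity
  and configurable grids.
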