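# eegrt — predicting reaction-time delays from pre-cue EEG bandpower

`eegrt` is an R package for a single-trial regression problem in
neuroergonomics: given the EEG recorded **immediately before** a visual
cue appears, predict how long the operator will take to respond to it.
It is aimed at researchers studying vigilance and operator readiness
(e.g. in flight- or driving-simulator sessions) who want a tested,
reproducible implementation of the bandpower-regression pipeline rather
than a pile of one-off scripts.

## The method

For each trial the 0.5 s pre-cue window (64 samples at 128 Hz, 14
channels) is decomposed into ten classical frequency bands (δ 1–4 Hz,
θ 4–8, α 8–12, three β subdivisions 12–24, high-β 24–28, γ₁ 32–36,
γ₂ 36–40, and a broad 8–30 Hz range) by zero-padded FFT filtering: the
demeaned window is padded 64 → 256 samples (0.5 Hz bins), out-of-band
Fourier amplitudes are set to zero, and the band signal is recovered by
the inverse transform. Each band signal x is summarized by its
log-variance bandpower

    logvar(x) = ln Var(x),

giving 14 × 10 = 140 features per trial, z-scored with training-set
statistics. Four regressors (LASSO, LASSO-LARS, RBF kernel ridge, RBF
SVR with correlation-ranked feature selection) are tuned by grid search
under 3-fold cross-validation minimizing MAE and evaluated over 11
random 75/25 train/test splits; the per-subject score is

    MAE_s = (1/11) Σ_{i=1}^{11} ( Σ_m |ŷ_m − y_m| / M ),

the mean over splits of the per-split mean absolute error. A
shuffled-label SVR — identical protocol, training targets permuted — is
the "no EEG information" control, and the statistical layer provides
per-session delay summaries with a Huber-IRLS robust trend over
time-in-session, one-way ANOVA across algorithms' absolute errors, and
pairwise t-tests.

Because such recordings are typically not redistributable, the package
includes a synthetic-session generator (normally distributed cue
intervals, band-limited oscillations plus 1/f noise, delays generated
from a configurable linear model on planted band powers) whose ground
truth is known, so the entire pipeline is validated by
parameter-recovery tests. See the methods vignette
(`vignettes/eegrt-methods.Rmd`) for every modelling and numerical
choice.

## Worked example

Simulate a two-hour session in which the alpha power of channel O1
drives the response delay (0.2 s per logvar unit, delay noise 0.05 s),
then test whether the pipeline finds that signal:

```r
library(eegrt)

cfg <- sim_config(seed = 11, coupling = c(O1_Alpha = 0.2))
session <- simulate_session(cfg)

epochs   <- extract_tsi(session$recording, session$events, tsi_len_samples = 64)
bands    <- decompose_epochs(epochs)                  # 10-band FFT decomposition
features <- build_feature_matrix(bands, session$events)
features
#> <feature_matrix: 53 trials x 140 features>

scheme <- split_scheme(n_repetitions = 11, base_seed = 42)
result <- evaluate_subject(features,
                           list(model_spec("svr_rbf"),
                                model_spec("shuffled_svr_rbf")),
                           scheme)
result
#> <eval_result: 2 algorithm(s), 11 repetitions>
#>         algorithm     mae_s    sd_ae_s  max_ae_s
#>           svr_rbf 0.0701122 0.05919609 0.3943373
#>  shuffled_svr_rbf 0.2335531 0.18016271 0.8648183

head(summarize_selected_features(result)$pooled, 3)
#>       feature count
#> 1    O1_Alpha    11
#> 2 AF4_MidBeta     9
#> 3    F8_Broad     8

summarize_delays(session$events)
#>       min_s median_s    max_s      sd_s slope_s_per_s    slope_p n_epochs
#> 1 0.5305277 1.037706 1.717386 0.2490832  2.446143e-05 0.09766652       53
```

Reading the output: the SVR predicts held-out delays with a 0.070 s mean
absolute error, versus 0.234 s for the shuffled control — a 3.3× gap, so
the model is using EEG information, not just fitting the average
response. The planted feature `O1_Alpha` is the top-ranked selection,
chosen in all 11 repetitions. The delay summary shows the session's
spread (0.53–1.72 s) and a robust trend of ~2.4e-5 s/s that is not
significant (p ≈ 0.10) — no systematic slowing over this simulated
session.

File-based workflows use `write_session()` / `load_recording()` (EDF or
long-form CSV) and `run_pipeline(run_config(...), out_dir)` (or a YAML
config via `read_run_config()`), which writes the feature matrix,
per-repetition results (`results.json`), report tables (CSV) and a
provenance manifest recording the window length (64 samples), padding
(192 zeros) and FFT length (256).

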