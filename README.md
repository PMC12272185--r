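# oscillage

Resting-state MEG shows some of the most reliable signatures of healthy
ageing in human neurophysiology: low-frequency (delta/theta) cortical power
declines across the adult lifespan while beta/gamma power rises, amplitude
envelope connectivity reorganises, and the whole pattern is predictive
enough that "brain age" can be regressed from it. `oscillage` packages that
analysis as a chain of tested, reusable stages for R users — researchers
who want the estimators (LCMV beamforming, leakage-corrected envelope
connectivity, PLS inference, bias-corrected brain-age regression) with
verifiable numerics rather than a monolithic pipeline script.

The stages, each exposed as plain functions with validated containers:

* **Forward model** — Sarvas single-sphere magnetic lead fields
  (`sphere_lead_field()`), with a deterministic helmet fixture
  (`make_sensor_array()`).
* **Preprocessing** — zero-phase Hamming-window FIR band-pass and notch
  filters, anti-aliased resampling, 10.24 s epoching, amplitude-based
  rejection (6000 fT peak-to-peak; 2000 fT above 110 Hz) and fixed-length
  trimming to 250 s (`fir_bandpass()`, `notch()`, `resample()`, `epoch()`,
  `reject_epochs()`, `trim_to_duration()`).
* **Source reconstruction** — LCMV beamformer per the minimum-variance
  unit-gain solution `w = C⁻¹h/(hᵀC⁻¹h)`, Tikhonov regularisation at 5% of
  the maximum singular value, max-power orientation selection, and
  neural-activity-index normalisation with unit-SD source time courses
  (`data_covariance()`, `tikhonov_regularise()`, `lcmv_scalar_weights()`,
  `apply_weights()`).
* **Spectral features** — Welch PSD over non-overlapping 4096-sample
  segments and relative band amplitudes over the canonical bands
  (delta 1–3, theta 4–8, alpha 9–12, beta 13–29, gamma 30–45 Hz)
  (`welch_psd()`, `band_relative_power()`, `cohort_band_power()`).
* **Connectivity** — symmetric (Löwdin) orthogonalisation to remove
  zero-lag leakage, Hilbert envelopes, 1 Hz block-mean downsampling and
  Pearson amplitude-envelope correlation (`symmetric_orthogonalise()`,
  `hilbert_envelope()`, `band_aec()`).
* **PLS inference** — SVD of `R = YᵀX` with permutation-tested singular
  values and bootstrap CIs of score–metadata Spearman correlations
  (`meg_pls()`), plus an exact-enumeration Mann–Whitney U for comparing
  salience magnitudes (`mann_whitney_u()`).
* **Brain age** — repeated stratified 10-fold cross-validation, in-fold
  standardisation, leave-one-out-tuned ridge (optionally AdaBoost.R2
  boosted), MAE/R² metrics and the slope/intercept bias correction
  `z′ = (z − b)/a` fitted on training folds only (`brain_age()`,
  `ridge_cv_fit()`, `adaboost_r2_fit()`).
* **Synthetic cohorts** — generators that plant parameterised age effects
  in band-limited source amplitudes and envelope couplings, at both the
  sensor level and the feature level, so every estimator can be checked
  against ground truth (`cohort_spec()`, `simulate_subject_sensors()`,
  `plant_coupled_sources()`, `simulate_feature_cohort()`).

`run_pipeline()` orchestrates all stages end-to-end from a flat-text
configuration and emits a checksummed run manifest.

## Worked example

Simulate a 200-subject feature-level cohort with planted lifespan effects,
test the age association with PLS, and fit the brain-age model:

```r
library(oscillage)

spec   <- cohort_spec(n_subjects = 200, seed = 42)
cohort <- simulate_feature_cohort(spec, n_regions = 78, seed = 42)
X <- as.matrix(cohort$power[, -1])            # 390 band-power features
Y <- cbind(age = cohort$metadata$age, sex = cohort$metadata$sex)

meg_pls(X, Y, n_perm = 500, n_boot = 500, seed = 1)
#> <meg_pls> n = 200 subjects, 390 features, 2 metadata columns
#>  component singular_value explained_cov p_value
#>          1         3252.0       0.99800   0.002
#>          2          144.5       0.00197   0.206

ba <- brain_age(X, cohort$metadata$age,
                scheme = cv_scheme(k = 10, repeats = 5, seed = 2))
summary(ba)
#> <brain_age> ridge_cv, 200 subjects, k = 10 x 5 repeats
#>   raw:       train MAE 3.66 +/- 0.44, test MAE 4.55 +/- 0.76 years
#>   corrected: train MAE 3.80 +/- 0.49, test MAE 4.71 +/- 0.80 years
#>   test R^2: raw 0.908, corrected 0.902
#>   prediction-on-age slope: raw test 0.903, corrected test 0.984
#>   brain-age delta: mean -0.00, SD 5.92 years
```

The first PLS component absorbs essentially all of the cross-covariance
with metadata and is significant under permutation (p = 0.002): that is the
planted age effect, recovered. The second component (dominated by the
unrelated sex column) is not significant. The brain-age model predicts held
out subjects with a test MAE of ~4.6 years against the generator's 5-year
noise floor; the raw prediction-on-age slope of 0.90 is the classic
regression-to-the-mean bias (young over-predicted, old under-predicted),
which the training-fold correction moves to 0.98 on test data without
degrading error. Each subject's `delta` (corrected prediction minus
chronological age) is the brain-age delta; positive values mean the brain
appears older than its years.

`plot(ba)` overlays raw and corrected test predictions against age with
their regression lines and the identity.

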