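---
title: "Methods: from sensor fields to brain age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sensor fields to brain age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscillage)
```

`oscillage` implements a resting-state MEG lifespan analysis as a chain of
testable stages: forward modelling, sensor-level cleaning, LCMV source
reconstruction, band-limited spectral power, leakage-corrected amplitude
envelope connectivity, PLS inference of age associations, and brain-age
regression with bias correction. Every stage can be exercised against a
synthetic cohort generator that plants known age effects, so the whole chain
is validated against ground truth rather than against itself. This vignette
explains the models, the parameter choices and their units, the numerical
decisions, and what the synthetic validation does and does not establish.

## Forward model

The conductor is a homogeneous sphere and sensors are point magnetometers;
the magnetic field of a current dipole then has the Sarvas closed form,
implemented in `sphere_lead_field()`. Positions are in metres (head-centred),
dipole moments in nA·m, fields in fT; the single scale constant tying these
together is the vacuum permeability prefactor with the nA·m → A·m and
T → fT conversions folded in. Two structural properties of this model shape
everything downstream:

* **Radial silence.** A dipole oriented along the radius produces no
  external field, so every channels × 3 lead field has effective rank 2.
* **Centre independence.** Gains depend only on geometry relative to the
  sphere centre, which the tests exploit via rotation equivariance.

`make_sensor_array()` builds a deterministic helmet fixture: radially
oriented magnetometers laid out on the upper hemisphere by a golden-angle
spiral (quasi-uniform for any channel count); the seed rotates the spiral's
azimuth. The default helmet radius is 0.12 m around a 0.09 m conductor —
plausible adult-head values; nothing downstream is sensitive to them.

## Sensor-level cleaning

All filters are symmetric odd-length Hamming-window FIR kernels applied in a
single pass with exact group-delay compensation, so they are zero-phase by
construction (verified by lag-0 cross-correlation peaks). The transition
bandwidth per band edge is `max(2 Hz, 0.25 × edge)` bounded by the edge
itself; under the ≈3.3/Δf length rule of the Hamming design this reproduces
a 3.3 s impulse response for the 1 Hz lower edge of the 1–150 Hz broadband
filter. The notch stage places a ±1.5 Hz stop band with 2 Hz transitions at
each line frequency (50 and 60 Hz by default), giving > 30 dB rejection at
the line while leaving tones 5 Hz away within 1 dB. Resampling (default
target 300 Hz) low-pass filters at 0.475 × the target rate and then
decimates (integer ratios) or spline-interpolates; upsampling is refused.

Cleaning then proceeds in fixed units of 10.24 s epochs (3072 samples at
300 Hz): epochs are rejected if any channel's broadband peak-to-peak
amplitude exceeds 6000 fT, or if the peak-to-peak of the epoch high-passed
above 110 Hz exceeds 2000 fT — the latter operationalises a muscle-artefact
criterion as an fT threshold on high-frequency content, the simplest reading
consistent with a peak-to-peak unit. Note that a genuinely broadband
transient (for example a single-sample spike) legitimately fires both rules;
the rejection log records `"ptp"`, `"hf"` or `"ptp+hf"` per epoch.
Finally `trim_to_duration()` keeps the *smallest* number of leading clean
epochs whose total reaches 250 s — 25 epochs (256 s) — so every subject
contributes identical data length; "reaching at least 250 s" is read as a
floor, since any fixed epoch count equalises subjects.

Automated artefact-component classification is out of scope (it requires
labelled ocular/cardiac exemplars that synthetic data cannot supply);
`remove_components()` is a pass-through hook that applies an externally
supplied projection instead.

## LCMV beamforming

The spatial filter for a source with lead field `H` and regularised sensor
covariance `C` is the classical minimum-variance unit-gain solution
`w = C⁻¹h / (hᵀC⁻¹h)` with `h = Hθ`. The covariance is computed from the
concatenated clean epochs (channel means removed, denominator n − 1) and
regularised by adding 5% of its maximum singular value to the diagonal,
which shifts every eigenvalue by exactly that amount and bounds the
condition number by `(1 + f)/f`.

The scalar orientation `θ` maximises beamformer output power among
unit-gain filters, i.e. minimises `θᵀ(HᵀC⁻¹H)θ` — the eigenvector of the
smallest eigenvalue. Because spherical-model lead fields are exactly rank 2,
the naive smallest eigenvector would select the magnetically silent radial
direction (`h = 0`, no unit-gain filter exists). The implementation
therefore restricts the eigenproblem to the numerically non-silent subspace
of `H` (SVD with a 1e-8 relative singular-value tolerance) and errors only
when that subspace is empty. For full-rank lead fields (as in the randomised
tests) this reduces to the plain smallest-eigenvector rule. The sign is
fixed by making the first non-zero component of `θ` positive.

Source time courses are `wᵀB` per epoch, concatenated. With the
neural-activity-index option the course is divided by `√(hᵀh)`, countering
the depth-dependent noise amplification of unit-gain filters — this is what
makes peak-power localisation meaningful across nodes. Every node is then
independently scaled to unit standard deviation; a consequence asserted in
the tests is that all downstream band-power and connectivity features are
exactly invariant to the NAI choice.

## Spectral power

`welch_psd()` averages one-sided modified periodograms over non-overlapping
Hann-tapered segments of 4096 samples (18 segments for 250 s at 300 Hz),
scaled so the PSD integrates to the signal variance (Parseval, verified to
5% on white noise). Band powers use the five canonical bands with 1 Hz
separating gaps — delta 1–3, theta 4–8, alpha 9–12, beta 13–29,
gamma 30–45 Hz. The band amplitude is the *mean* of √PSD over the in-band
bins (band edges inclusive); relative power divides each amplitude by the
sum of the five, so the five values per node sum to exactly 1 and gap bins
plus content above 45 Hz are excluded from the denominator. Two consequences
worth noting: a flat spectrum yields 1/5 per band regardless of band width
(the mean, unlike a sum, does not reward wide bands), and relative power is
exactly invariant to rescaling the input. Whether "relative" should instead
normalise by total broadband power is genuinely underdetermined; the
five-band-sum choice is isolated in `band_relative_power()` and makes the
sum-to-one invariant testable.

## Leakage-corrected envelope connectivity

Per band the chain is: zero-phase band-pass filter → symmetric
orthogonalisation → Hilbert envelopes → edge trim → 1 Hz block means →
Pearson correlation, in that order (orthogonalisation acts on the full-rate
band-limited signals, envelopes are extracted afterwards).

Symmetric orthogonalisation removes the zero-lag correlations that
instantaneous field spread induces between reconstructed nodes. It finds
the closest set (least squares) of mutually orthogonal signals to the
demeaned inputs, treating all nodes equivalently: alternating a polar/SVD
projection onto the nearest orthonormal frame with a per-node scale refit,
iterated until the squared residual changes by less than 1e-10 of the total
input power (cap 300 iterations, with a convergence error carrying the
residual). Because outputs are linear combinations of the inputs, zero
means are preserved and pairwise Pearson correlations vanish at machine
precision; already-orthogonal inputs are fixed points, and permuting input
rows permutes outputs identically. Rank-deficient inputs are refused with
the deficient dimension named — orthogonalisation cannot manufacture
dimensions that field spread has collapsed.

The analytic signal is computed by zeroing negative FFT frequencies; its
modulus is the envelope. The first and last 2 s of each envelope are trimmed
before downsampling to suppress the FFT wrap-around edge artefact — the
bound is small against the 250 s analysis window and recorded here as a
package choice. Envelopes are downsampled by non-overlapping 1-s block
means (robust to envelope spectra, standard for this connectivity measure)
rather than decimation filters; 250 s yields 250 envelope samples. The
connectivity matrix is the Pearson correlation over node pairs, symmetric
with the diagonal fixed at 0 (self-coupling is undefined after
orthogonalisation); zero-variance nodes are flagged and set missing.

## PLS inference

With subjects × features `X` (band power and/or vectorised upper-triangle
connectivity, band-major) and subjects × metadata `Y` (age in years, sex
coding), both column-standardised, the cross-product `R = YᵀX` is decomposed
by SVD `R = UΔVᵀ`. Columns of `V` are feature saliences, columns of `U`
metadata saliences, and subject scores are `Lx = XV`, `Ly = YU`; each
singular value equals `(n − 1)` times the covariance of its paired scores,
an identity the tests verify numerically, and the first pair maximises that
covariance (checked against 10 000 random unit-vector pairs). Component
signs are fixed by making each `V` column's largest-magnitude element
positive.

Significance uses permutation: rows of `X` are shuffled jointly with `Y`
held fixed (preserving the metadata correlation structure), the SVD is
recomputed, and `p_i = (1 + #{δ*_i ≥ δ_i}) / (1 + n_perm)` — valid and
bounded below by `1/(1 + n_perm)`; the default 1000 permutations mirrors the
bootstrap count since no separate figure is prescribed. Uncertainty in the
score–metadata associations uses bootstrap resampling of subjects with
replacement (default 1000): each resample's SVD is sign-aligned to the
original solution (no Procrustes rotation — a deliberate simplification,
adequate for well-separated components and recorded as a limitation),
Spearman rank correlations between `Ly` columns and metadata columns are
collected, and percentile intervals returned. Resamples that produce a
constant column are redrawn and counted. One caveat the tests encode: with
a single metadata column, `Ly` is a scalar multiple of that column and the
Spearman correlation degenerates to ±1, so calibration statements require
at least two metadata columns.

The band-power versus connectivity salience comparison uses a two-sided
Mann–Whitney U on absolute saliences. `U` counts pairs where the first
group exceeds the second (ties half). For total sample size ≤ 20 the null
distribution is enumerated exhaustively over group assignments of the
observed values — exact even under ties — with the two-sided p-value being
the null mass at least as far from `n₁n₂/2` as observed; larger samples use
the normal approximation with the standard tie correction.

## Brain-age regression

Cross-validation is repeated stratified K-fold (defaults k = 10, 10
repeats): ages are binned at 0/22.5/45/67.5/90 years, subjects are shuffled
within bins and dealt round-robin to folds, so per-fold bin composition
deviates from the global one by at most one subject per bin. An occupied
bin with a single subject raises a stratification error; bins smaller than
k are allowed (some folds simply lack that bin), which keeps modest uniform
lifespan cohorts — whose 18–22.5 corner holds only a handful of subjects —
valid. Within each fold, features are standardised with training-fold
statistics only, the model is fitted on training rows, and predictions are
stored for both splits; per-subject summaries average test-fold and
train-fold predictions separately across repeats.

The reference model is ridge regression with the penalty chosen by exact
leave-one-out MSE computed from the SVD of the centred design without
refitting. Numerically the LOO shortcut is evaluated in complement form —
residuals and `1 − h_ii` built from `α/(d² + α)` directly, with the
unpenalised intercept contributing `1/n` to every hat diagonal — because
the textbook subtraction form suffers catastrophic cancellation at small
penalties on over-parameterised designs and silently selects interpolating
fits. The grid spans 1e−3…1e5 (13 log-spaced points), wide enough to include
the strong-regularisation regime. `adaboost_r2_fit()` provides the boosted
variant: per round a weighted bootstrap refit of the base model, linear
loss normalised by its maximum, multiplicative weight update, early stop at
average loss 0.5, and weighted-median prediction.

Age-prediction bias — over-predicting the young, under-predicting the old,
visible as a prediction-on-age slope below 1 — is corrected by fitting
`z = a·c + b` by OLS on the *training* predictions and inverting,
`z′ = (z − b)/a`, applied identically to train and test rows using
train-fold coefficients only (no leakage). On the training fold the
corrected predictions regress on age with slope exactly 1 and intercept 0
(an algebraic property of inverting an OLS fit, asserted at 1e-9); on test
folds the correction helps only insofar as train and test bias agree, so
the corrected test error may move slightly in either direction — the
pipeline asserts it never degrades materially. Model comparison ranks
candidates by test MAE plus the absolute train–test MAE gap, a selection
key that penalises overfit models, which benefit least from this correction
scheme.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions: ages uniform on 18–83 years
(an optional bimodal mode thins the 40–60 range, mimicking lifespan cohorts
with sparse middle age), and per-band source amplitudes that are linear in
age — delta/theta/alpha declining (−0.006/−0.005/−0.002 units/yr from
baselines 1.0/1.0/1.2), beta/gamma rising (+0.006/+0.005 from 0.8/0.6).
Monotonic linear trajectories are the simplest shape consistent with what
lifespan MEG shows; the slopes are free parameters chosen so amplitudes
remain positive across the range, since no usable generative effect sizes
are published. Negative planted amplitudes are clipped at zero with a
warning.

Sources are band-limited Gaussian noise, not sinusoids — resting MEG has
stochastic narrowband dynamics, and a sinusoid's envelope is degenerate —
superposed on a 1/f background, projected through the spherical lead fields
(instantaneous mixing), with white sensor noise added (default 50 fT SD).

Envelope coupling is planted by giving two independent-phase carriers a
shared slow (0.05–0.3 Hz) log-normal amplitude modulator; sharing weight is
solved by root-finding *on the realised 1 Hz envelopes* so the measured
coupling hits the target ρ, while zero-lag correlation of the raw signals
stays near zero. The modulator log-SD (1.25) caps the achievable coupling
around 0.9 — residual carrier-envelope noise that survives 1-s averaging —
and targets beyond the ceiling fall back to the closest attainable value
with a warning.

`simulate_feature_cohort()` shortcuts the signal chain for the inference
stages. Each subject receives a latent "functional age" equal to
chronological age plus N(0, σ) noise shared across all features, and every
feature adds independent noise on top. The shared component is what bounds
achievable prediction accuracy: with independent noise only, averaging 390
features would drive the best attainable error to zero. The default
σ = 5·√(π/2) ≈ 6.27 years makes the best attainable mean absolute error
exactly 5 years, a realistic figure for MEG-based age prediction, and gives
the validation a meaningful oracle to compare against. Connectivity
tensors plant their age trends on the Fisher-z scale and back-transform, so
matrices are symmetric, zero-diagonal and bounded in (−1, 1).

What passing these tests shows — and does not. The generator emulates the
statistical structure the analysis assumes: linear age effects, narrowband
stochastic sources, instantaneous mixing, stationary noise. It contains no
ocular/cardiac/muscle artefacts, no head movement, no non-stationarity, no
multi-site scanner differences, and no nonlinear age trajectories. Passing
validates the estimators and their algebra under the assumed model; it does
not certify performance on real multi-site recordings.

## Problem sizes and determinism

The validation suite runs at deliberately chosen desk scales: 100 random
30-channel beamformer instances against 10 000 random unit-gain filters;
single-dipole recovery over 20 seeds at 0 dB SNR with 42 candidate nodes
and 260 s recordings; orthogonalisation of 20-node × 75 000-sample inputs;
envelope-coupling recovery over 20 seeds of 250 s; PLS null calibration
over 200 replicates at n = 200, p = 100 with 199 permutations each (the
permutation count trades resolution for replicate count — p-values of
0.005 resolution suffice for an α = 0.05 calibration check); and brain age
on 300 subjects × 390 features with 10 × 10-fold cross-validation. All
randomness flows through explicit seeds; library code snapshots and
restores the caller's RNG state, and identical configurations reproduce
bit-identical pipeline outputs (checksummed in the run manifest).

## Known limitations

Sensors are ideal point magnetometers — no gradiometer baselines, coil
integration or reference-array interference modelling. The spherical
conductor cannot probe errors that realistic head geometry introduces.
Bootstrap components are sign-aligned but not rotation-aligned, so closely
spaced singular values can mix across resamples. The AEC generator cannot
plant couplings much above 0.9 at 1 Hz. And the brain-age oracle bound is a
property of the generator's noise decomposition; on real data no such
oracle exists and model comparison must rely on the train/test gap key
alone.
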