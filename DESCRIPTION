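Package: oscillage
Title: Lifespan Analysis of MEG Oscillatory Power, Envelope Connectivity and Brain Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a resting-state MEG lifespan
    analysis pipeline: spherical-conductor forward modelling, sensor-level
    cleaning (zero-phase FIR filtering, notch, resampling, fixed-length
    epoching with amplitude-based rejection), LCMV beamformer source
    reconstruction with Tikhonov regularisation and max-power orientation
    selection, Welch band-limited relative power, leakage-corrected amplitude
    envelope connectivity via symmetric orthogonalisation, partial least
    squares inference of age associations with permutation and bootstrap
    resampling, and brain-age regression with repeated stratified
    cross-validation and slope/intercept bias correction. Includes a
    synthetic cohort generator that plants parameterised age effects in
    band-limited source activity and envelope coupling so every stage can be
    validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
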