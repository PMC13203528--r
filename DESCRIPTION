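Package: dualfall
Title: Dual-Frame Pre-Impact Fall Detection from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for pre-impact fall detection from waist-worn
    inertial measurement units sampled at 100 Hz. Implements Madgwick
    gradient-descent attitude estimation with free-fall gating and
    body-to-global coordinate transformation, pre-impact trial
    truncation with reverse sliding-window sampling, training-set-only
    augmentation (jitter, scaling, time warping), a lightweight
    four-branch classifier built from depthwise-separable convolutions
    with squeeze-and-excitation attention and a causal dilated temporal
    convolutional network, subject-grouped cross-validation with an
    AdamW / cosine-warm-restart recipe, trial-wise max-voting
    evaluation, rolling-inference lead-time measurement, and a
    deterministic synthetic IMU trial generator for end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
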