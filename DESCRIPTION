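Package: lombardlab
Title: Simulation and Acoustic Analysis of Noise-Induced Vocal Modification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying noise-induced vocal modification (the Lombard
    effect and spectral changes) in primate calls. Generates calibrated
    band-limited noise playback treatments, synthesizes tamarin-like
    combination long calls and chirps under a parameterized noise-response
    model, measures calls with noise-subtracted sound pressure levels,
    Welch power spectral densities with noise-spectrum subtraction, harmonic
    peak detection, spectral-tilt ratios, fundamental-frequency contours and
    durations, and fits the repeated-measures analysis of covariance
    (noise level by bandwidth, random subject intercept) used in playback
    experiments. Includes a seeded end-to-end experiment simulator so every
    measurement and statistic can be checked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
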