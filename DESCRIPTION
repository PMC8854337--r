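Package: emgforce
Title: Muscle Force Estimation and Activity Classification from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline pipeline for estimating knee-extensor muscle force from
    multi-channel surface electromyography (sEMG). Provides a protocol-faithful
    synthetic recording generator (contraction/rest cycles with known ground-truth
    activation), the standard sEMG pre-processing chain (DC removal, Butterworth
    band-pass, powerline notch, half-wave rectification, linear-envelope smoothing,
    normalisation), windowed time-domain feature extraction (MAV, RMS, VAR, WL, ZC,
    SSC, IEMG), active/rest classification with a Gaussian-kernel support vector
    machine and a random forest with out-of-bag error estimation, epsilon-insensitive
    support vector regression of force from EMG envelopes, a genetic algorithm for
    wrapper feature selection and hyper-parameter tuning, and an evaluation harness
    with trial-holdout and pooled 70/30 protocols, 10-fold cross-validation,
    confusion matrices and regression error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    ranger,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
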