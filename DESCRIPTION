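Package: vagfusion
Title: Vibroarthrographic Signal Features and Dynamic Weighted Classifier Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and ensemble classification for knee-joint
    vibroarthrographic (VAG) vibration signals. Implements greedy matching
    pursuit over a periodized Daubechies wavelet-packet dictionary with a
    signal-to-noise-ratio stopping rule, fixed-threshold turns counting on
    Butterworth low-pass filtered records, Hjorth-style form factors and
    related time-domain statistics, least-squares support vector machines
    trained by solving the Karush-Kuhn-Tucker linear system, bootstrap
    aggregation of component classifiers, and a dynamic weighted fusion rule
    with closed-form per-sample weights. Includes a reproducible synthetic
    two-class VAG cohort generator, quadratic Renyi-entropy subset selection,
    ROC evaluation with Hanley-McNeil standard errors, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
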