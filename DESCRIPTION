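Package: stopcsp
Title: Stop-Signal Behavior, Cortical Silent Period Extraction, and Robust
    Brain-Behavior Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates adaptive stop-signal task sessions under the independent
    horse-race model, synthesizes stimulus-locked surface EMG with known motor
    evoked potential (MEP) and cortical silent period (CSP) ground truth, and
    provides the full analysis chain linking the two: integration-method SSRT
    estimation with go-omission replacement, consensus participant-exclusion
    screening, envelope-based MEP/CSP detection with a pre-stimulus
    return-to-baseline rule, skipped (robust) Pearson correlation with a
    minimum-covariance-determinant center and percentile-bootstrap inference,
    and leave-one-out cross-validation with a permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
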