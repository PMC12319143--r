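Package: stopreach
Title: Reach-Trajectory Stop-Signal Analysis and Food-Intake Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies of late-stage inhibitory control measured with
    three-dimensional hand-trajectory recordings in immersive stop-signal
    tasks. Simulates complete synthetic cohorts (minimum-jerk reaches with an
    adaptive stop-signal staircase, gaze-collision streams, web-based
    stop-signal and single-category implicit-association sessions, and
    ad-libitum intake generated from a known sparse linear model); extracts
    per-trial biometric parameters (peak velocity and acceleration, stopping
    latency, braking distance, maximal approach displacement, initiation
    time, dwell times); scores stop-signal sessions with the integration
    method with replacement of response omissions and implicit-association
    sessions with the standardized D-score algorithm; provides paired tests,
    2x2 repeated-measures ANOVA with partial eta squared, and correlation
    summaries; and predicts intake from the standardized feature set with
    ordinary least squares, elastic-net, and Lasso regression selected by
    cross-validated mean absolute error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
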