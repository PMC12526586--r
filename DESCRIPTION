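Package: fmapr
Title: Instrumented Functional Mobility Analysis for Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for instrumented functional mobility
    assessment in Parkinson's disease. Reads optical motion-capture
    trials (C3D or plain-text marker tables) and pressure-mat
    center-of-pressure exports, conditions marker trajectories (gap
    filling, spike mitigation, zero-lag Butterworth filtering), detects
    gait events, segments Timed-Up-and-Go-style movement sequences into
    tasks (sit-to-stand, walking, doorway passage, 180-degree turn,
    functional reach, stand-to-sit), and computes a full biomechanical
    metric set: trunk inclination and dynamics, joint flexion, segmental
    yaw turning profiles, toe-off/heel-strike angles, foot clearance,
    spatiotemporal gait parameters, arm-swing asymmetry, stance geometry,
    center-of-pressure displacement, and freezing-like-event detection
    against a walking-speed baseline. Includes ordinal performance-score
    aggregation, a simultaneity index for postural-locomotion-manual
    sequences, study-level statistics (predictive-mean-matching multiple
    imputation with mean pooling, family-wise Bonferroni alpha
    bookkeeping, one-way random-effects intraclass correlation,
    group-by-protocol ANCOVA and repeated-measures phase analysis), and a
    parameterized full-body trial simulator with ground truth for
    validation without capture hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
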