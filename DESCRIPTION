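Package: ttswing
Title: Single-Camera Biomechanical Quantification of Table Tennis Forehand Strokes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pose-landmark-based kinematics pipeline for table tennis forehand
    strokes captured with a single camera. Takes 33-landmark position time
    series (MediaPipe Pose topology, 100 Hz), applies FIR low-pass filtering,
    two-factor real-world scaling and dynamic origin calibration, computes
    landmark velocities, segment plane angles and joint angles, segments the
    forward-swing phase from wrist-velocity inflection points, extracts
    per-stroke kinematic summaries (range, mean/peak/impact velocity), predicts
    ball speed from annotated six-frame ball trajectories with an RBF support
    vector regression, and relates kinematics to ball speed with
    repeated-measures (within-subject) and weighted between-subject
    correlations. Includes reliability metrics (ICC, normalized DTW similarity,
    cosine similarity), Bland-Altman agreement analysis, curve-feature group
    comparison, a Monte-Carlo correlation power calculator, and a synthetic
    stroke-cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
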