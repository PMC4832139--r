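Package: psykernel
Title: Psychophysical Kernels for Trajectory-Displacement Detection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolchain for continuous visual
    displacement-detection experiments. Simulates a multi-item linear-motion
    display with scheduled trajectory displacements, generates synthetic
    observer gaze traces and button presses from a ground-truth detection
    kernel, detects and classifies target-directed saccades from 60 Hz gaze
    data with an adaptive acceleration threshold, bins trials into detection
    categories, estimates psychophysical kernels (covariance ellipses of the
    non-detection density in motion-normalized displacement space) by reverse
    correlation, and provides repeated-measures ANOVA with sphericity
    handling for group-level comparison of kernel properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
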