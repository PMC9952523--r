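Package: broilergait
Title: Spatiotemporal and Three-Dimensional Locomotion Metrics for
    Gait-Scored Broilers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the walking ability of individual
    broiler chickens on a gait-scoring platform from top-view imagery and
    keypoint tracks.  Rectifies platform images (Canny edge detection,
    Hough line detection, rotation about the image centroid, cropping),
    assembles three-dimensional trajectories from planar back-keypoint
    tracks at 30 Hz and depth frames at 10 Hz, extracts sixteen
    locomotive-behavior metrics (per-axis absolute speed and
    acceleration, forward-moving bout durations, half-cycle lateral body
    oscillation durations), and compares the metrics across three-point
    gait-score categories with one-way ANOVA, pooled standard errors,
    and Fisher LSD letter groupings.  Includes a seeded synthetic-data
    generator that emulates gait-score-dependent walking styles,
    platform images, pose-estimation CSV exports, and depth streams so
    the full pipeline can be exercised and validated without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
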