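Package: handmotion
Title: Grid-Based Hand-Motion Analytics for Surgical Training Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of bimanual 21-landmark hand-tracking streams recorded
    during surgical training procedures (e.g. cadaveric mastoidectomy).
    Provides a validated session format for per-frame hand-landmark records,
    a calibrated 3x3 grid mapping scene semantics (surgical field, instrument
    table, microscope handles, trash bin) onto the camera frame, detection
    performance accounting, per-cell dwell-time statistics with heatmaps,
    and segmentation of workflow events (instrument changes, microscope
    adjustments, trash visits) from grid-cell excursions of the occupancy
    landmark. A semi-Markov behaviour simulator with Ornstein-Uhlenbeck
    hand trajectories, brightness-driven tracking dropout and null-handedness
    records generates realistic sessions with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
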