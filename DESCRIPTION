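Package: limbuse
Title: Quantifying Upper-Limb Use from Wearable Kinematics and EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying upper-limb use during activities of daily
    living from paired-limb hand trajectories, accelerations and forearm
    surface EMG. Implements two complementary analysis tracks: time-based
    segmentation into fixed-duration quants with accelerometer activity
    counts, muscle activity counts and log-ratio statistics; and path-based
    segmentation of continuous trajectories into completed movements via
    arc-length parametrization, with per-movement kinematic and EMG metrics
    combined into a bimanual movement parameter (BMP) that classifies
    movements as unimanual, bimanual or unclassified. Includes synthetic
    session generators (minimum-jerk strokes, hexagon tracing) with ground
    truth for validation, CSV readers and writers, and batch pipeline entry
    points with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
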