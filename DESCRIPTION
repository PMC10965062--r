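Package: videogait
Title: Video-Based Clinical Gait Analysis from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for markerless clinical gait analysis from single-camera
    video processed with a 25-keypoint human pose estimator. Reads and writes
    OpenPose BODY_25 per-frame JSON, tracks a participant across frames,
    corrects left-right limb label swaps, gap-fills and low-pass filters
    keypoint trajectories, detects heel-strikes and toe-offs from frontal,
    sagittal, or motion-capture signals, and computes spatiotemporal gait
    parameters. Frontal-view step lengths use a monocular depth-from-pixel-size
    model: the torso's apparent pixel size relative to a known reference depth
    yields the walker's depth-change under a pinhole camera. Includes
    condition-specific clinical metrics (step asymmetry, trunk inclination),
    sagittal lower-limb joint kinematics, Bland-Altman agreement statistics
    for validating one measurement system against another, and a fully
    ground-truthed synthetic 3D walker projected through pinhole cameras for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
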