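Package: reachtrack
Title: Video-Based Hand Movement Kinematics and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline pipeline for a low-cost video method of quantifying
    goal-directed hand movements. Renders and detects a high-contrast
    circle fiducial (calibrated gray thresholding, connected-component
    circle discrimination, sub-pixel intensity-weighted centroids),
    replays the two-target repetitive reaching protocol as a target-square
    state machine, cuts trajectories into travel and endpoint segments,
    computes five kinematic metrics (mean speed, mean absolute
    acceleration, percent speed error, endpoint center offset, intertarget
    path accuracy), and assesses test-retest reliability with ICC(2,k)
    from two-way ANOVA without replication and Pearson correlations with
    Fisher-z intervals. Includes a synthetic trial and cohort generator
    with configurable age effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
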