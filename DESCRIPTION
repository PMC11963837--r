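Package: fapa
Title: Automated Inference of Facial Paralysis from Mouse Facial Videography
Version: 1.0.0
Authors@R:
    person("fapa", "developers", email = "fapa-dev@example.org", role = c("aut", "cre"))
Description: Video-based quantification of facial movement in head-fixed mice
    and automated inference of reversible and irreversible facial paralysis.
    Tracks painted-whisker kinematics (angle traces, movement cycles,
    changepoints, amplitude classes, spectrograms), describes facial motion
    with histogram-of-oriented-gradients (HOG) frame descriptors reduced to a
    scalar frame-difference series, and applies threshold-based binary
    decision models to flag paralysis at the frame, session, and timeline
    level. Also builds basal and stimulus-evoked facial-expression prototypes
    from HOG descriptors, and computes peristimulus time histograms, baseline
    z-scores, and cross-covariance between neural firing and facial-movement
    traces. Includes a deterministic synthetic-data generator (face videos
    with zone-wise programmable motion, whisker traces with injury schedules,
    motion-coupled Poisson spike trains) so the full pipeline is testable
    without animal data, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
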