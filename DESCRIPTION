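Package: vogkit
Title: Modular Video-Oculography: Pupil, Glint, Torsion and Dual-Purkinje Tracking
Version: 0.1.0
Authors@R: person("vogkit", "developers", role = c("aut", "cre"),
    email = "vogkit@example.org")
Description: A modular framework for video-based eye tracking. Provides
    interchangeable tracking pipelines (dark-pupil detection by centroid,
    convex hull or direct ellipse fitting; corneal-reflection (glint)
    detection for the pupil-CR method; ocular torsion by iris polar
    unwrapping and circular cross-correlation; digital dual-Purkinje P1/P4
    tracking), calibration by geometric eye model or regression against
    fixation targets, lossless raw video input/output, a bounded FIFO frame
    buffer with ordered multi-worker emission, frame-by-frame data
    recording, offline batch reprocessing, a minimal remote-control command
    protocol, and a synthetic infrared eye-image renderer with analytic
    ground truth for end-to-end validation without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
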