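Package: rollgaze
Title: Model-Based Point-of-Gaze Estimation with Relative-Roll Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Geometric point-of-gaze (PoG) estimation for hand-held,
    infrared, model-based eye trackers. Reconstructs the visual axis of
    the eye from the pupil centre and the centre of corneal curvature via
    an eye-fixed coordinate frame, compensates for the relative roll
    (R-Roll) between device and eye, and intersects the axis with the
    display plane to obtain the PoG. Includes the closed-form law for the
    roll-induced angular error as a function of the optical-visual axis
    offsets, a synthetic fixation-session simulator with feature and
    head-tracker noise, subject calibration of the axis offsets by
    nonlinear least squares, and an evaluation harness comparing
    roll-compensated and uncompensated estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
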