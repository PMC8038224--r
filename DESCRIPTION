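Package: lumbarload
Title: Ambulatory Estimation of L5/S1 Lumbar Net Moments from Wearable
    EMG and Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the three-dimensional net moment at the
    L5/S1 intervertebral joint during physically demanding work from
    wearable sensor data: four bilateral trunk surface-EMG channels and
    inertial measurement units on the sternum, sacrum and arms. Implements
    sensor-to-segment calibration from functional movements, EMG amplitude
    (envelope) estimation with tap-marker stream synchronization, a
    top-down linked-segment inverse-dynamics model scaled by subject
    anthropometry that supplies supervised training targets, a per-session
    feed-forward neural network (16 inputs, 31 sigmoid hidden units, 3
    linear outputs) mapping EMG envelopes plus sternum and sacrum
    kinematics to the 3D net moment, and the discriminant-validity
    statistics used to evaluate such estimators (curve agreement, task
    descriptives, direction-split analysis, normality-gated paired
    testing). A forward simulator generates physiologically plausible
    calibration, known-load and work-task sessions with ground-truth
    moments so the full pipeline can be exercised and validated without
    recorded human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
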