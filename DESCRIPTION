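Package: imukin
Title: Lower-Extremity Joint Kinematics from Inertial Measurement Units
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An open workflow for estimating lower-extremity joint kinematics
    from body-worn inertial measurement units (IMUs) over long durations.
    Raw triaxial gyroscope, accelerometer and magnetometer signals are fused
    into per-sensor orientations with Madgwick or Mahony complementary
    filters (or plain strap-down gyroscope integration as a drift baseline);
    sensor-to-segment rotational offsets are registered from a standing
    calibration pose; and joint angles are solved per frame by orientation
    tracking inverse kinematics on a constrained pelvis-torso-leg kinematic
    chain, minimising a weighted sum of squared axis-angle differences
    between measured and model-predicted virtual IMU orientations, with
    distal sensors downweighted. Includes rule-based pre-screening of
    unrealistic sensor streams, drift quantification via per-minute RMS
    regression, agreement statistics, and a seeded synthetic-trial generator
    for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
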