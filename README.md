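# imukin

Lower-extremity joint kinematics from body-worn inertial measurement units
(IMUs), over durations long enough that drift — the unbounded accumulation of
orientation error from integrating gyroscope noise and bias — is the central
problem. The package is written for biomechanists and rehabilitation
researchers who want an open, scriptable alternative to proprietary IMU
suits: raw gyroscope/accelerometer/magnetometer streams in, named joint
angles out, with the error-monitoring tools needed to trust a 10-minute
recording.

## The method

Per sensor, raw signals are fused into orientation estimates by a
complementary filter (Madgwick gradient-descent or Mahony PI feedback;
plain strap-down gyro integration is kept as the drift baseline). After a
5-s standing calibration that registers each sensor to its host segment as a
fixed rotational offset, joint angles are estimated per frame by
orientation-tracking inverse kinematics on a constrained kinematic chain
(6-dof pelvis, 3-dof lumbar and hips, pin knees and ankles; 19 coordinates,
8 sensor sites). Writing the measured sensor orientation as
\(^N R_i^{exp}\) and the model-predicted virtual-IMU orientation as
\(^N R_i^{vir}(q)\), each sensor's tracking error is the axis-angle rotation
angle

$$\theta_i = \cos^{-1}\frac{\operatorname{tr} R_i - 1}{2},
\qquad R_i = \bigl(^N R_i^{exp}\bigr)^{\mathsf T}\; {}^N R_i^{vir}(q),$$

and the joint angles solve

$$\min_q \sum_{i \in \mathrm{IMUs}} w_i\,\theta_i^2,$$

with distal sensors downweighted (shanks 0.5, feet 0.25) because sensors
near the floor suffer the worst magnetic disturbance. The same \(\theta_i\)
residuals drive a pre-screening step that excludes physiologically
unrealistic sensor streams (any \(\theta_i > 45^\circ\), or a mean 60-ms bin
range \(> 30^\circ\), within the first 10 s), and drift is quantified as the
slope of a linear fit to per-minute RMS differences. A seeded synthetic-trial
generator (ground-truth joint angles plus consistent noisy IMU signals)
closes the loop for validation without any external data.

## Worked example

Simulate a 60-s walking trial with consumer-MEMS noise, then run the whole
chain and compare with the generator's ground truth:

```r
library(imukin)

model <- build_default_model()
traj  <- generate_trajectory(
  trajectory_config(duration_s = 60, activity = "walk", seed = 1), model)
sim   <- synthesize_imu(model, traj,
                        offsets = random_offsets(names(imu_sites(model)),
                                                 seed = 2),
                        noise = noise_model(), seed = 3)

orientations <- lapply(sim$imu, run_filter,
                       config = filter_config("madgwick", beta = 0.1))
measured     <- lapply(orientations, average_orientation, window = c(0, 5))
registration <- calibrate(model, measured)

report  <- screen_trial(model, registration, orientations)
weights <- apply_screen(default_ik_weights(registration), report)
fit     <- ik_trajectory(model, registration, orientations, weights)
summary(fit)
```

```
Orientation-tracking IK fit: 6000 frames, 59.99 s
Converged: 6000/6000 frames (mean 2.5 LM iterations, mean cost 2.24e-05 rad^2)
...
IK orientation differences, RMS per sensor (deg):
       sensor weight  rms_deg
1  pelvis_imu   1.00 3.47e-07
2   torso_imu   1.00 9.09e-08
3 thigh_r_imu   1.00 1.04e-01
4 thigh_l_imu   1.00 1.03e-01
5 shank_r_imu   0.50 1.81e-01
6 shank_l_imu   0.50 1.76e-01
7  foot_r_imu   0.25 2.01e-01
8  foot_l_imu   0.25 2.03e-01
```

The per-sensor RMS `theta` values are the IK orientation differences: the
residual disagreement, in degrees, between what each sensor measured and
where the fitted skeleton put its virtual counterpart — near zero here
because the only corruption is sensor noise. Comparing against ground truth:

```r
truth <- traj$q
truth[, -(4:6)] <- truth[, -(4:6)] * 180 / pi   # radians -> degrees
compare_report(fit, list(time = traj$t, coordinates = truth), window_s = 20)
```

```
Kinematic comparison over 2 windows of 20 s
            angle median_rms_deg iqr_deg
    ankle_flexion           0.13    0.01
    hip_adduction           0.14    0.02
      hip_flexion           0.14    0.01
     hip_rotation           0.18    0.03
     knee_flexion           0.13    0.01
 ...
drift slopes: 0.002 to 0.052 deg/min
Pearson r: 0.99 to 1.00
```

Every joint angle is recovered to ≈ 0.1–0.2° RMS with drift slopes
indistinguishable from zero; on a 10-minute trial the same pipeline holds
per-minute-RMS drift below 0.2 deg/min while gyro-only integration drifts at
>10 deg/min (see the acceptance driver below). The whole run, including the
one-line pipeline variant `run_pipeline(list(seed = 1))`, is deterministic
under its seed.

## Documentation

The methods vignette (`vignettes/imu-kinematics.Rmd`) documents the model
and its assumptions, every tunable parameter with units and defaults, the
numerical choices in the filters and the IK solver, what the synthetic
generator does and does not emulate, and the known limitations.
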