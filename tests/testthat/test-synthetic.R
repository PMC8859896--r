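# Synthetic-trial generator: trajectories, signal synthesis, study fixture.

test_that("static_pose trajectories are identically zero with calibration labels first", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 10, activity = "static_pose"), m)
  expect_true(all(traj$q == 0))
  expect_equal(unique(traj$labels[traj$t < 5]), "calibration")
  expect_equal(unique(traj$labels[traj$t >= 5]), "static_pose")
})

test_that("gait parameters are echoed in the generated knee profile", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 30, cadence_spm = 100,
                      amplitudes = list(knee_flexion = c(30, 30))), m)
  knee <- traj$q[, "knee_flexion_r"] * 180 / pi
  steady <- traj$t > 8
  # range 60 degrees peak to peak
  expect_equal(diff(range(knee[steady])), 60, tolerance = 1)
  # stride period = 120 / cadence = 1.2 s
  k <- knee[steady]
  shift <- round(1.2 * 100)
  expect_lt(max(abs(k[-(1:shift)] - k[1:(length(k) - shift)])), 0.5)
})

test_that("generation is deterministic under a fixed seed", {
  m <- build_default_model()
  make <- function() {
    traj <- generate_trajectory(
      trajectory_config(duration_s = 8, activity = "walk", seed = 9), m)
    synthesize_imu(m, traj, noise = noise_model(), seed = 9)
  }
  s1 <- make(); s2 <- make()
  expect_identical(s1$imu$foot_l_imu$gyro, s2$imu$foot_l_imu$gyro)
  expect_identical(s1$imu$torso_imu$mag, s2$imu$torso_imu$mag)
  expect_identical(s1$truth$pelvis_imu$q, s2$truth$pelvis_imu$q)
})

test_that("amplitudes beyond the model bounds are rejected", {
  m <- build_default_model()
  expect_error(generate_trajectory(
    trajectory_config(duration_s = 10,
                      amplitudes = list(hip_adduction = c(0, 80))), m),
    "bounds")
})

test_that("static synthesis: zero gyro, 1 g specific force, rotated field", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 8, activity = "static_pose"), m)
  offs <- random_offsets(names(imukin:::imu_sites(m)), seed = 81)
  sim <- synthesize_imu(m, traj, offs, noise_free(), mag_field = c(0.4, 0, -0.3))
  for (id in c("pelvis_imu", "foot_l_imu")) {
    s <- sim$imu[[id]]
    expect_lt(max(abs(s$gyro)), 1e-12)
    expect_equal(sqrt(rowSums(s$accel^2)), rep(9.81, length(s$t)),
                 tolerance = 1e-9)
    R <- quat_to_matrix(sim$truth[[id]]$q[1, ])
    expect_lt(max(abs(s$mag[1, ] - drop(t(R) %*% c(0.4, 0, -0.3)))), 1e-12)
  }
})

test_that("strap-down integration of synthetic gyro reproduces the truth (forward-inverse consistency)", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 60, rate_hz = 100, activity = "walk"), m)
  sim <- synthesize_imu(m, traj, noise = noise_free())
  for (id in c("thigh_r_imu", "foot_l_imu")) {
    o <- integrate_gyro(sim$imu[[id]], sim$truth[[id]]$q[1, ])
    ang <- imukin:::qmat_angle(o$q, sim$truth[[id]]$q) * 180 / pi
    expect_lt(max(ang), 0.2)
  }
})

test_that("a planted constant gyro bias produces the closed-form linear drift", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 60, activity = "static_pose"), m)
  sim <- synthesize_imu(m, traj, noise = noise_model(
    gyro_noise_density = 0, gyro_bias = 0.01, accel_noise = 0,
    mag_noise_rel = 0), seed = 82)
  s <- sim$imu$shank_r_imu
  bias_hat <- colMeans(s$gyro)  # static trial: the gyro reads the bias
  o <- integrate_gyro(s, sim$truth$shank_r_imu$q[1, ])
  n <- length(s$t)
  drift <- orientation_difference(o$q[n, ], sim$truth$shank_r_imu$q[n, ])
  expected <- sqrt(sum(bias_hat^2)) * (s$t[n] - s$t[1])
  expect_lt(abs(drift - expected) / expected, 0.1)
})

test_that("accelerometer magnitude over static segments is 1 g within noise tolerance", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 20, activity = "walk"), m)
  sim <- synthesize_imu(m, traj, noise = noise_model(), seed = 83)
  s <- sim$imu$torso_imu
  calib <- s$t < 4.5
  mn <- mean(sqrt(rowSums(s$accel[calib, ]^2)))
  expect_lt(abs(mn - 9.81), 3 * 0.05 / sqrt(sum(calib)) + 0.01)
})

test_that("magnetic disturbance on one sensor leaves every other signal bit-identical", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 12, activity = "walk"), m)
  nm0 <- noise_model()
  nm1 <- noise_model(mag_disturbance = list(
    list(sensor = "foot_r_imu", amp_deg = 30, t_on = 6, t_off = 10)))
  s0 <- synthesize_imu(m, traj, noise = nm0, seed = 84)
  s1 <- synthesize_imu(m, traj, noise = nm1, seed = 84)
  expect_identical(s0$imu$foot_r_imu$gyro, s1$imu$foot_r_imu$gyro)
  expect_identical(s0$imu$foot_r_imu$accel, s1$imu$foot_r_imu$accel)
  expect_false(identical(s0$imu$foot_r_imu$mag, s1$imu$foot_r_imu$mag))
  for (id in setdiff(names(s0$imu), "foot_r_imu")) {
    expect_identical(s0$imu[[id]]$mag, s1$imu[[id]]$mag)
    expect_identical(s0$imu[[id]]$gyro, s1$imu[[id]]$gyro)
  }
})

test_that("foot heading disturbance hurts hip rotation more than knee flexion", {
  fx <- walk_fixture()
  ors <- fx$orientations
  qz <- axis_angle_to_quat(c(0, 0, 1), 30 * pi / 180)
  post <- ors$foot_r_imu$t > 5
  Q <- ors$foot_r_imu$q
  Q[post, ] <- imukin:::qmat_multiply(
    matrix(qz, sum(post), 4, byrow = TRUE), Q[post, , drop = FALSE])
  ors$foot_r_imu <- orientation_series("foot_r_imu", ors$foot_r_imu$t, Q)
  fit <- ik_trajectory(fx$model, fx$registration, ors)
  truth <- truth_degrees(fx$traj)
  err <- function(cn) sqrt(mean((fit$coordinates[, cn] - truth[, cn])^2))
  expect_gt(err("hip_rotation_r"), err("knee_flexion_r"))
})

test_that("the study fixture has the expected composition", {
  fx <- cached("fixture15", make_study_fixture(seed = 5, duration_s = 15))
  expect_length(fx$walking$imu, 8L)
  expect_length(fx$offsets, 8L)
  for (R in fx$offsets) {
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_gt(det(R), 0)
  }
  # trials regenerate identically from the same seed
  fx2 <- make_study_fixture(seed = 5, duration_s = 15)
  expect_identical(fx$walking$imu$shank_l_imu$gyro,
                   fx2$walking$imu$shank_l_imu$gyro)
  # the corrupted variant differs from the clean one only on the slipped foot
  expect_false(identical(fx$corrupted$imu$foot_r_imu$gyro,
                         fx$walking$imu$foot_r_imu$gyro))
})

test_that("the movement-cycle trial stays in bounds and visits its activities", {
  m <- build_default_model()
  traj <- generate_trajectory(
    trajectory_config(duration_s = 60, activity = "activity_cycle"), m)
  expect_true(all(traj$q >= matrix(m$coords$lb, nrow(traj$q), 19,
                                   byrow = TRUE) - 1e-9))
  expect_true(all(traj$q <= matrix(m$coords$ub, nrow(traj$q), 19,
                                   byrow = TRUE) + 1e-9))
  expect_setequal(unique(traj$labels),
                  c("calibration", "sit", "stand", "stairs", "side_step",
                    "walk", "run"))
  # sitting actually flexes hips and knees
  sit <- traj$labels == "sit" & traj$t > 8
  expect_gt(min(traj$q[sit, "knee_flexion_r"]) * 180 / pi, 45)
})
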