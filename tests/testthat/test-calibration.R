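# Sensor-to-segment calibration and heading alignment.

test_that("a sensor aligned with its segment calibrates to an identity offset", {
  m <- build_default_model()
  fk <- forward_kinematics(m, default_pose(m))
  measured <- lapply(imukin:::imu_sites(m), function(seg)
    matrix_to_quat(fk$orientation[[seg]]))
  names(measured) <- names(imukin:::imu_sites(m))
  reg <- calibrate(m, measured)
  for (id in names(measured))
    expect_lt(max(abs(reg$offsets[[id]] - diag(3))), 1e-12)
})

test_that("planted offsets are recovered through the synthetic round trip", {
  fx <- walk_fixture()
  for (id in names(fx$offsets)) {
    err <- rotation_angle(relative_rotation(fx$registration$offsets[[id]],
                                            fx$offsets[[id]]))
    expect_lt(err, 1e-4)  # limited only by filter initialisation accuracy
  }
  # exact recovery when calibrating directly on the true orientations
  m <- fx$model
  measured <- lapply(fx$sim$truth, function(os) os$q[1, ])
  reg <- calibrate(m, measured)
  for (id in names(measured)) {
    err <- rotation_angle(relative_rotation(reg$offsets[[id]],
                                            fx$offsets[[id]]))
    expect_lt(err, 1e-10)
  }
})

test_that("calibration reproduces the measured orientations at q_cal by construction", {
  m <- build_default_model()
  set.seed(41)
  q_cal <- rand_pose(m, 20)
  measured <- stats::setNames(lapply(seq_len(8), function(i) rand_quat()),
                              names(imukin:::imu_sites(m)))
  reg <- calibrate(m, measured, q_cal = q_cal)
  vir <- virtual_imu_orientations(m, q_cal, reg)
  for (id in names(measured))
    expect_lt(orientation_difference(matrix_to_quat(vir[[id]]),
                                     measured[[id]]), 1e-9)
})

test_that("calibrate reports missing sensors by id", {
  m <- build_default_model()
  expect_error(calibrate(m, list(pelvis_imu = c(1, 0, 0, 0))),
               "torso_imu")
})

test_that("average_orientation: constant window, double cover, noisy mean", {
  set.seed(42)
  q <- rand_quat()
  expect_lt(orientation_difference(
    average_orientation(matrix(q, 10, 4, byrow = TRUE)), q), 1e-12)
  # window of q and -q still averages to q
  expect_lt(orientation_difference(
    average_orientation(rbind(q, -q, q, -q)), q), 1e-12)
  # 1-degree noise over a 500-sample window, 100 seeded trials: mean within
  # 0.2 degrees of truth
  for (trial in 1:100) {
    qs <- t(vapply(1:500, function(i) {
      ax <- stats::rnorm(3)
      quat_multiply(q, axis_angle_to_quat(ax, stats::rnorm(1, 0, pi / 180)))
    }, numeric(4)))
    m <- average_orientation(qs)
    expect_lt(orientation_difference(m, q) * 180 / pi, 0.2)
  }
})

test_that("average_orientation flags dispersed windows", {
  q <- c(1, 0, 0, 0)
  spread <- rbind(q, axis_angle_to_quat(c(0, 0, 1), 40 * pi / 180))
  expect_warning(average_orientation(spread), "dispersion")
  expect_error(average_orientation(spread, on_unstable = "error"),
               "dispersion")
})

test_that("heading_align removes heading disagreement and nothing else", {
  m <- build_default_model()
  fk <- forward_kinematics(m, default_pose(m))
  set.seed(43)
  offsets <- random_offsets(names(imukin:::imu_sites(m)), seed = 44)
  measured <- lapply(names(imukin:::imu_sites(m)), function(id)
    matrix_to_quat(fk$orientation[[imukin:::imu_sites(m)[[id]]]] %*%
                     offsets[[id]]))
  names(measured) <- names(imukin:::imu_sites(m))
  reg <- calibrate(m, measured)

  # consistent headings: alignment leaves the registration unchanged
  reg2 <- heading_align(reg, "pelvis_imu")
  for (id in names(measured))
    expect_lt(max(abs(reg2$offsets[[id]] - reg$offsets[[id]])), 1e-9)

  # a +15 degree heading (earth-Z) perturbation of one sensor is removed
  pert <- measured
  qz15 <- axis_angle_to_quat(c(0, 0, 1), 15 * pi / 180)
  pert$foot_r_imu <- quat_multiply(qz15, pert$foot_r_imu)
  reg3 <- heading_align(reg, "pelvis_imu", measured = pert)
  vir <- virtual_imu_orientations(m, reg$q_cal, reg3)
  expect_lt(orientation_difference(matrix_to_quat(vir$foot_r_imu),
                                   pert$foot_r_imu) * 180 / pi, 1e-6)

  # an inclination perturbation is deliberately NOT removed
  pert2 <- measured
  qx15 <- axis_angle_to_quat(c(1, 0, 0), 15 * pi / 180)
  pert2$foot_r_imu <- quat_multiply(qx15, pert2$foot_r_imu)
  reg4 <- heading_align(reg, "pelvis_imu", measured = pert2)
  vir4 <- virtual_imu_orientations(m, reg$q_cal, reg4)
  expect_gt(orientation_difference(matrix_to_quat(vir4$foot_r_imu),
                                   pert2$foot_r_imu) * 180 / pi, 5)
  expect_error(heading_align(reg, "nope_imu"), "nope_imu")
})

test_that("IK on the calibration frame returns the calibration pose", {
  m <- build_default_model()
  set.seed(45)
  q_cal <- rand_pose(m, 15)
  offsets <- random_offsets(names(imukin:::imu_sites(m)), seed = 46)
  fk <- forward_kinematics(m, q_cal)
  measured <- lapply(names(imukin:::imu_sites(m)), function(id)
    matrix_to_quat(fk$orientation[[imukin:::imu_sites(m)[[id]]]] %*%
                     offsets[[id]]))
  names(measured) <- names(imukin:::imu_sites(m))
  reg <- calibrate(m, measured, q_cal = q_cal)
  sol <- ik_frame(m, reg, measured, q_init = q_cal)
  expect_lt(sol$cost, 1e-12)
  free <- m$coords$free
  expect_lt(max(abs(sol$pose[free] - q_cal[free])) * 180 / pi, 1e-3)
})

test_that("registration round trips through YAML and JSON", {
  fx <- walk_fixture()
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    save_registration(fx$registration, path)
    reg2 <- load_registration(path)
    expect_equal(reg2$mapping, fx$registration$mapping)
    for (id in names(fx$registration$offsets))
      expect_lt(max(abs(reg2$offsets[[id]] - fx$registration$offsets[[id]])),
                1e-9)
    expect_equal(unname(reg2$q_cal), unname(fx$registration$q_cal))
  }
})
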