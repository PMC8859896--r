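# Orientation-tracking inverse kinematics: the central estimator.

noiseless_measured <- function(model, registration, pose) {
  vir <- virtual_imu_orientations(model, pose, registration)
  lapply(vir, matrix_to_quat)
}

test_that("ik_frame recovers the generating pose exactly", {
  fx <- walk_fixture()
  m <- fx$model
  reg <- fx$registration
  set.seed(51)
  for (rep in 1:5) {
    q_true <- rand_pose(m, 30)
    measured <- noiseless_measured(m, reg, q_true)
    # starting at the optimum: stays there
    at_opt <- ik_frame(m, reg, measured, q_init = q_true)
    expect_lt(at_opt$cost, 1e-12)
    # starting from the neutral pose: converges into the same minimum
    sol <- ik_frame(m, reg, measured)
    expect_lt(sol$cost, 1e-8)
    free <- m$coords$free
    expect_lt(max(abs(sol$pose[free] - q_true[free])) * 180 / pi, 0.1)
  }
})

test_that("a single pin joint has the closed-form solution", {
  m <- pin_model()
  reg <- calibrate(m, list(base_imu = c(1, 0, 0, 0),
                           arm_imu = c(1, 0, 0, 0)))
  for (phi in c(-1.2, -0.3, 0.7, 2.1)) {
    measured <- list(arm_imu = axis_angle_to_quat(c(0, 0, 1), phi))
    sol <- ik_frame(m, reg, measured, weights = c(arm_imu = 1))
    expect_equal(unname(sol$pose["hinge_angle"]), phi, tolerance = 1e-8)
    expect_lt(sol$cost, 1e-14)
  }
})

test_that("the cost function is the weighted sum of squared angles", {
  m <- pin_model()
  reg <- calibrate(m, list(base_imu = c(1, 0, 0, 0),
                           arm_imu = c(1, 0, 0, 0)))
  measured <- list(arm_imu = axis_angle_to_quat(c(0, 0, 1), 0.2))
  expect_equal(ik_cost(m, reg, measured, c(arm_imu = 1),
                       c(hinge_angle = 0)), 0.04, tolerance = 1e-12)
  expect_equal(ik_cost(m, reg, measured, c(arm_imu = 1),
                       c(hinge_angle = 0.2)), 0, tolerance = 1e-15)
  expect_equal(ik_cost(m, reg, measured, c(arm_imu = 2.5),
                       c(hinge_angle = 0)), 0.1, tolerance = 1e-12)
})

test_that("the reported per-frame cost equals the R-side objective at the solution", {
  fx <- walk_fixture()
  set.seed(52)
  q_true <- rand_pose(fx$model, 25)
  measured <- noiseless_measured(fx$model, fx$registration, q_true)
  # perturb one sensor so the optimum has non-zero residual
  measured$foot_r_imu <- quat_multiply(axis_angle_to_quat(c(0, 0, 1), 0.3),
                                       measured$foot_r_imu)
  w <- default_ik_weights(fx$registration)
  sol <- ik_frame(fx$model, fx$registration, measured, weights = w,
                  q_init = q_true)
  expect_equal(sol$cost,
               ik_cost(fx$model, fx$registration, measured, w, sol$pose),
               tolerance = 1e-9)
  expect_equal(sol$cost, sum(w * (sol$theta * pi / 180)^2),
               tolerance = 1e-9)
})

test_that("the cost decreases along the negative numeric gradient", {
  fx <- walk_fixture()
  set.seed(53)
  q_true <- rand_pose(fx$model, 25)
  measured <- noiseless_measured(fx$model, fx$registration, q_true)
  w <- default_ik_weights(fx$registration)
  free <- which(fx$model$coords$free)
  for (rep in 1:5) {
    pose <- rand_pose(fx$model, 25)
    g <- vapply(free, function(j) {
      ph <- pose; ph[j] <- ph[j] + 1e-6
      (ik_cost(fx$model, fx$registration, measured, w, ph) -
         ik_cost(fx$model, fx$registration, measured, w, pose)) / 1e-6
    }, numeric(1))
    step <- pose
    step[free] <- step[free] - 1e-4 * g / max(abs(g))
    expect_lt(ik_cost(fx$model, fx$registration, measured, w, step),
              ik_cost(fx$model, fx$registration, measured, w, pose))
  }
})

test_that("zero-weight sensors leave the solution bit-identical to removal", {
  fx <- walk_fixture()
  ors <- lapply(fx$orientations, function(o)
    orientation_series(o$sensor_id, o$t[1:500], o$q[1:500, ]))
  # corrupt the right foot stream badly
  qz <- axis_angle_to_quat(c(0, 0, 1), 45 * pi / 180)
  ors$foot_r_imu$q <- imukin:::qmat_multiply(
    matrix(qz, 500, 4, byrow = TRUE), ors$foot_r_imu$q)
  w <- default_ik_weights(fx$registration)
  w["foot_r_imu"] <- 0
  fit_w0 <- ik_trajectory(fx$model, fx$registration, ors, weights = w)
  fit_rm <- ik_trajectory(fx$model, fx$registration,
                          ors[names(ors) != "foot_r_imu"], weights = w)
  expect_identical(fit_w0$coordinates, fit_rm$coordinates)
})

test_that("scaling all weights leaves the argmin unchanged and scales the cost", {
  fx <- walk_fixture()
  set.seed(54)
  q_true <- rand_pose(fx$model, 25)
  measured <- noiseless_measured(fx$model, fx$registration, q_true)
  measured$shank_l_imu <- quat_multiply(axis_angle_to_quat(c(1, 0, 0), 0.2),
                                        measured$shank_l_imu)
  w <- default_ik_weights(fx$registration)
  s1 <- ik_frame(fx$model, fx$registration, measured, weights = w,
                 q_init = q_true)
  s2 <- ik_frame(fx$model, fx$registration, measured, weights = 7 * w,
                 q_init = q_true)
  expect_lt(max(abs(s1$pose - s2$pose)) * 180 / pi, 1e-4)
  expect_equal(s2$cost / s1$cost, 7, tolerance = 1e-3)
})

test_that("increasing a sensor's weight pulls the solution toward it (two-sensor pin toy)", {
  m <- pin_model()
  # both sensors on the arm, disagreeing about the hinge angle
  mapping <- c(arm_imu = "arm", arm_imu2 = "arm")
  measured_cal <- list(arm_imu = c(1, 0, 0, 0), arm_imu2 = c(1, 0, 0, 0))
  reg <- calibrate(m, measured_cal, mapping = mapping)
  phi_a <- 0.2; phi_b <- 0.9
  measured <- list(arm_imu = axis_angle_to_quat(c(0, 0, 1), phi_a),
                   arm_imu2 = axis_angle_to_quat(c(0, 0, 1), phi_b))
  sols <- vapply(c(0.1, 1, 10), function(wb) {
    s <- ik_frame(m, reg, measured, weights = c(arm_imu = 1, arm_imu2 = wb))
    unname(s$pose["hinge_angle"])
  }, numeric(1))
  expect_true(all(diff(abs(sols - phi_b)) < 0))
  expect_true(all(sols > phi_a & sols < phi_b))
})

test_that("trajectory IK recovers a noiseless walking trial within solver tolerance", {
  fx <- walk_fixture()
  fit <- ik_trajectory(fx$model, fx$registration, fx$orientations)
  truth <- truth_degrees(fx$traj)
  free_rot <- setdiff(colnames(fit$coordinates),
                      c("pelvis_tx", "pelvis_ty", "pelvis_tz"))
  for (cn in free_rot) {
    rmse <- sqrt(mean((fit$coordinates[, cn] - truth[, cn])^2))
    expect_lt(rmse, 0.5)
  }
  expect_true(all(fit$theta >= 0, na.rm = TRUE))
})

test_that("missing samples drop the sensor's term for those frames only", {
  fx <- walk_fixture()
  ors <- lapply(fx$orientations, function(o)
    orientation_series(o$sensor_id, o$t[1:300], o$q[1:300, ]))
  ors$thigh_l_imu$q[100:120, ] <- NA_real_
  fit <- ik_trajectory(fx$model, fx$registration, ors)
  expect_true(all(is.na(fit$theta[100:120, "thigh_l_imu"])))
  expect_true(all(is.finite(fit$coordinates)))
  expect_true(all(is.finite(fit$theta[1:99, "thigh_l_imu"])))
})

test_that("warm starting does not introduce jitter beyond the input's own motion", {
  fx <- walk_fixture()
  fit <- ik_trajectory(fx$model, fx$registration, fx$orientations)
  truth <- truth_degrees(fx$traj)
  for (cn in c("hip_flexion_r", "knee_flexion_l", "pelvis_rotation")) {
    max_jump_fit <- max(abs(diff(fit$coordinates[, cn])))
    max_jump_truth <- max(abs(diff(truth[, cn])))
    expect_lt(max_jump_fit, max_jump_truth + 0.1)
  }
})

test_that("the fitted object exposes the standard methods", {
  fx <- walk_fixture()
  ors <- lapply(fx$orientations, function(o)
    orientation_series(o$sensor_id, o$t[1:200], o$q[1:200, ]))
  fit <- ik_trajectory(fx$model, fx$registration, ors)
  expect_s3_class(fit, "imu_ik")
  expect_equal(dim(coef(fit)), c(200L, 19L))
  expect_equal(dim(residuals(fit)), c(200L, 8L))
  expect_output(print(fit), "imu_ik")
  s <- summary(fit)
  expect_output(print(s), "RMS per sensor")
  df <- as.data.frame(fit)
  expect_equal(names(df)[1], "time")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "theta"))
})
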