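# Sensor fusion: initialisation, filter steps, full runs, and error metrics.

static_sample <- function(q, gravity = 9.81, field = c(0.4, 0, -0.3)) {
  R <- quat_to_matrix(q)
  list(accel = drop(t(R) %*% c(0, 0, gravity)), mag = drop(t(R) %*% field))
}

test_that("initial_orientation implements the TRIAD construction", {
  expect_equal(initial_orientation(c(0, 0, 9.81), c(1, 0, 0)), c(1, 0, 0, 0),
               tolerance = 1e-12)
  # magnetic field along sensor +y: sensor is yawed -90 deg from north
  q_yaw <- initial_orientation(c(0, 0, 9.81), c(0, 1, 0))
  expect_lt(orientation_difference(q_yaw, axis_angle_to_quat(c(0, 0, 1),
                                                             -pi / 2)), 1e-12)
  # sensor x axis pointing up
  q <- initial_orientation(c(9.81, 0, 0), c(0.3, 0.5, -0.4))
  expect_lt(max(abs(quat_rotate(quat_conjugate(q), c(0, 0, 1)) -
                      c(1, 0, 0))), 1e-9)
  # reconstructs a random static orientation exactly
  set.seed(11)
  qt <- rand_quat()
  s <- static_sample(qt)
  expect_lt(orientation_difference(initial_orientation(s$accel, s$mag), qt),
            1e-9)
  expect_error(initial_orientation(c(0, 0, 0), c(1, 0, 0)), "zero")
  expect_error(initial_orientation(c(0, 0, 9.81), c(0, 0, 5)), "parallel")
})

test_that("madgwick_step is a fixed point on consistent static input", {
  set.seed(12)
  qt <- rand_quat()
  s <- static_sample(qt)
  q2 <- madgwick_step(qt, c(0, 0, 0), s$accel, s$mag, dt = 0.01, beta = 0.1)
  expect_lt(orientation_difference(q2, qt), 1e-9)
})

test_that("madgwick_step with beta 0 is exact one-step gyro integration", {
  q <- c(1, 0, 0, 0)
  om <- 0.8
  for (i in 1:100)
    q <- madgwick_step(q, c(0, 0, om), c(0, 0, 9.81), c(0.4, 0, -0.3),
                       dt = 0.01, beta = 0)
  expect_equal(orientation_difference(q, axis_angle_to_quat(c(0, 0, 1),
                                                            om * 1)),
               0, tolerance = 1e-4)
})

test_that("madgwick converges from a 20-degree static perturbation", {
  set.seed(13)
  qt <- rand_quat()
  s <- static_sample(qt)
  ax <- stats::rnorm(3)
  q <- quat_multiply(qt, axis_angle_to_quat(ax, 20 * pi / 180))
  for (i in 1:1000)
    q <- madgwick_step(q, c(0, 0, 0), s$accel, s$mag, dt = 0.01, beta = 0.1)
  expect_lt(orientation_difference(q, qt) * 180 / pi, 1)
})

test_that("madgwick_step warns and skips the correction on zero accel", {
  expect_warning(q2 <- madgwick_step(c(1, 0, 0, 0), c(0, 0, 0.5), c(0, 0, 0),
                                     c(0.4, 0, -0.3), dt = 0.01, beta = 0.1),
                 "zero-norm")
  expect_equal(q2, madgwick_step(c(1, 0, 0, 0), c(0, 0, 0.5), c(0, 0, 9.81),
                                 c(0.4, 0, -0.3), dt = 0.01, beta = 0))
})

test_that("mahony_step: gain-off equivalence, fixed point, bias estimation", {
  set.seed(14)
  qt <- rand_quat()
  s <- static_sample(qt)
  # kp = ki = 0 equals beta-0 madgwick (pure integration) to 1e-12
  g <- c(0.3, -0.2, 0.5)
  m1 <- mahony_step(qt, g, s$accel, s$mag, dt = 0.01, kp = 0, ki = 0)
  m2 <- madgwick_step(qt, g, s$accel, s$mag, dt = 0.01, beta = 0)
  expect_lt(orientation_difference(m1$q, m2), 1e-12)
  # static fixed point
  m3 <- mahony_step(qt, c(0, 0, 0), s$accel, s$mag, dt = 0.01, kp = 0.5,
                    ki = 0.1)
  expect_lt(orientation_difference(m3$q, qt), 1e-9)
  # constant gyro bias is recovered by the integral term within 5%
  bias <- c(0.05, -0.03, 0.02)
  q <- qt
  bs <- c(0, 0, 0)
  for (i in 1:6000) {
    st <- mahony_step(q, bias, s$accel, s$mag, dt = 0.01, kp = 1, ki = 0.3,
                      bias_state = bs)
    q <- st$q
    bs <- st$bias_state
  }
  expect_lt(max(abs(bs - bias)), 0.05 * sqrt(sum(bias^2)))
})

test_that("integrate_gyro: constant input closed forms", {
  t <- seq(0, 1, by = 0.01)
  zeros <- matrix(0, length(t), 3)
  s0 <- imu_series("s", t, zeros, cbind(0, 0, rep(9.81, length(t))),
                   cbind(0.4, 0, rep(-0.3, length(t))))
  set.seed(15)
  q0 <- rand_quat()
  o <- integrate_gyro(s0, q0)
  expect_equal(max(quat_angle_rows(o$q, matrix(q0, length(t), 4,
                                               byrow = TRUE))), 0)
  # constant 90 deg/s about z for 1 s -> 90 deg heading within 0.1 deg
  gy <- matrix(rep(c(0, 0, pi / 2), each = length(t)), ncol = 3)
  s1 <- imu_series("s", t, gy, s0$accel, s0$mag)
  o1 <- integrate_gyro(s1, c(1, 0, 0, 0))
  expect_lt(abs(orientation_difference(
    o1$q[length(t), ], axis_angle_to_quat(c(0, 0, 1), pi / 2))) * 180 / pi,
    0.1)
})

test_that("gyro-noise-driven orientation error grows with duration", {
  set.seed(16)
  mean_terminal_err <- vapply(c(5, 20, 60), function(dur) {
    t <- seq(0, dur, by = 0.01)
    errs <- vapply(1:8, function(r) {
      gy <- matrix(stats::rnorm(length(t) * 3, sd = 0.05), ncol = 3)
      s <- imu_series("s", t, gy, cbind(0, 0, rep(9.81, length(t))),
                      cbind(0.4, 0, rep(-0.3, length(t))))
      o <- integrate_gyro(s, c(1, 0, 0, 0))
      orientation_difference(o$q[length(t), ], c(1, 0, 0, 0))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_terminal_err) > 0))
})

test_that("run_filter on a noiseless static series returns the rest orientation", {
  set.seed(17)
  qt <- rand_quat()
  s <- static_sample(qt)
  t <- seq(0, 10, by = 0.01)
  n <- length(t)
  ser <- imu_series("s", t, matrix(0, n, 3),
                    matrix(s$accel, n, 3, byrow = TRUE),
                    matrix(s$mag, n, 3, byrow = TRUE))
  for (alg in c("madgwick", "mahony", "gyro_only")) {
    o <- run_filter(ser, filter_config(alg))
    expect_lt(max(quat_angle_rows(o$q, matrix(qt, n, 4, byrow = TRUE))),
              1e-6)
  }
  expect_error(run_filter(imu_series("s", t[1:100], matrix(0, 100, 3),
                                     matrix(s$accel, 100, 3, byrow = TRUE),
                                     matrix(s$mag, 100, 3, byrow = TRUE)),
                          filter_config(init_window_s = 5)),
               "shorter than the initialisation window")
})

test_that("gain-zero configurations coincide with strap-down integration", {
  fx <- walk_fixture()
  ser <- fx$sim$imu$thigh_r_imu
  qt <- fx$sim$truth$thigh_r_imu$q[1, ]
  o_mad <- run_filter(ser, filter_config("madgwick", beta = 0), q0 = qt)
  o_mah <- run_filter(ser, filter_config("mahony", kp = 0, ki = 0), q0 = qt)
  o_gyr <- integrate_gyro(ser, qt)
  expect_lt(max(quat_angle_rows(o_mad$q, o_gyr$q)), 1e-9)
  expect_lt(max(quat_angle_rows(o_mah$q, o_gyr$q)), 1e-9)
})

test_that("fused walking orientations track the synthetic truth within 2 degrees RMS", {
  fx <- walk_fixture()
  for (id in names(fx$orientations)) {
    est <- fx$orientations[[id]]
    ref <- fx$sim$truth[[id]]
    ang <- quat_angle_rows(est$q[est$t > 5, ], ref$q[ref$t > 5, ]) * 180 / pi
    expect_lt(sqrt(mean(ang^2)), 2)
  }
})

test_that("frame contract: the estimated rotation maps measured specific force to earth up", {
  fx <- walk_fixture()
  o <- fx$orientations$pelvis_imu
  a1 <- fx$sim$imu$pelvis_imu$accel[1, ]
  up <- quat_rotate(o$q[1, ], a1 / sqrt(sum(a1^2)))
  expect_lt(acos(min(1, up[3])) * 180 / pi, 1)
})

test_that("disabling the magnetometer preserves inclination while heading drifts", {
  fx <- walk_fixture()
  ser <- fx$sim$imu$thigh_r_imu
  # corrupt the magnetometer beyond use
  set.seed(18)
  ser$mag <- ser$mag + matrix(stats::rnorm(length(ser$t) * 3, sd = 5), ncol = 3)
  o <- run_filter(ser, filter_config("madgwick", beta = 0.1,
                                     mag_divisor = 1e9L),
                  q0 = fx$sim$truth$thigh_r_imu$q[1, ])
  truth <- fx$sim$truth$thigh_r_imu$q
  # inclination error: angle between estimated and true sensor up-axis
  up_est <- imukin:::qmat_rotate(imukin:::qmat_conjugate(o$q),
                                 matrix(c(0, 0, 1), length(ser$t), 3,
                                        byrow = TRUE))
  up_tru <- imukin:::qmat_rotate(imukin:::qmat_conjugate(truth),
                                 matrix(c(0, 0, 1), length(ser$t), 3,
                                        byrow = TRUE))
  incl <- acos(pmin(1, rowSums(up_est * up_tru))) * 180 / pi
  expect_lt(sqrt(mean(incl^2)), 2)
})

test_that("fusion_error computes per-window RMS of the orientation difference", {
  t <- seq(0, 180, by = 0.05)
  n <- length(t)
  q_id <- matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE)
  ref <- orientation_series("s", t, q_id)
  expect_equal(fusion_error(ref, ref, 60), c(0, 0, 0))
  # constant 10-degree offset
  off <- axis_angle_to_quat(c(0, 1, 0), 10 * pi / 180)
  est <- orientation_series("s", t, matrix(off, n, 4, byrow = TRUE))
  expect_equal(fusion_error(est, ref, 60), c(10, 10, 10), tolerance = 1e-9)
  # sinusoidal 0..20 degree error: RMS matches the numerically computed RMS
  th <- 10 * (1 - cos(2 * pi * t / 6))
  qs <- cbind(cos(th * pi / 360), 0, 0, sin(th * pi / 360))
  est2 <- orientation_series("s", t, qs)
  got <- fusion_error(est2, ref, 60)
  want <- imukin:::window_rms(th, t, 60)
  expect_equal(got, want, tolerance = 0.01)
  expect_error(fusion_error(est, orientation_series("s", t + 0.5, q_id)),
               "time-aligned")
})

test_that("the 40 Hz pipeline with gain 0.025 stays within 2x of the 100 Hz pipeline", {
  model <- build_default_model()
  rms_for <- function(rate, beta) {
    traj <- generate_trajectory(
      trajectory_config(duration_s = 30, rate_hz = rate, activity = "walk"),
      model)
    sim <- synthesize_imu(model, traj, noise = noise_model(), seed = 19)
    errs <- vapply(names(sim$imu), function(id) {
      o <- run_filter(sim$imu[[id]], filter_config("madgwick", beta = beta))
      keep <- o$t > 5
      sqrt(mean((imukin:::qmat_angle(o$q[keep, ], sim$truth[[id]]$q[keep, ]) *
                   180 / pi)^2))
    }, numeric(1))
    mean(errs)
  }
  r100 <- rms_for(100, 0.1)
  r40 <- rms_for(40, 0.025)
  expect_lt(r40, 2 * r100 + 0.1)
})

test_that("slerp resampling reproduces values at original timestamps and interpolates between", {
  fx <- walk_fixture()
  os <- fx$orientations$shank_l_imu
  sub <- seq(1, length(os$t), by = 2)
  rs <- resample_orientations(os, os$t[sub])
  expect_lt(max(quat_angle_rows(rs$q, os$q[sub, ])), 1e-9)
  mid <- resample_orientations(os, os$t[10] + 0.005)
  expect_lt(orientation_difference(mid$q[1, ], os$q[10, ]),
            orientation_difference(os$q[11, ], os$q[9, ]) + 1e-9)
})
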