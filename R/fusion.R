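# Sensor fusion: per-sensor orientation estimation from raw gyro/accel/mag
# streams via Madgwick or Mahony complementary filters, plus plain strap-down
# gyroscope integration as the drift baseline.
#
# Conventions (documented once, used everywhere):
#   * earth frame: right-handed, Z up, X = horizontal projection of the
#     magnetic field at initialisation (magnetic north), Y completes;
#   * accelerometers measure specific force: a static, level sensor reads
#     (0, 0, +9.81) m/s^2;
#   * orientations are sensor-to-earth: v_earth = R(q) v_sensor.

#' Construct an IMU time series
#'
#' @param sensor_id Character label for the sensor.
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param gyro,accel,mag `n x 3` numeric matrices: angular velocity (rad/s),
#'   specific force (m/s^2) and magnetic field (any consistent unit), all in
#'   the sensor frame.
#' @param rate_hz Nominal sampling rate; inferred from the median timestep
#'   when omitted.
#' @return An object of class `imu_series`.
#' @export
imu_series <- function(sensor_id, t, gyro, accel, mag, rate_hz = NULL) {
  t <- as.numeric(t)
  gyro <- as_mat3(gyro, "gyro")
  accel <- as_mat3(accel, "accel")
  mag <- as_mat3(mag, "mag")
  n <- length(t)
  if (n < 2L) stop("an imu_series needs at least 2 samples")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (nrow(gyro) != n || nrow(accel) != n || nrow(mag) != n)
    stop("gyro/accel/mag must have one row per timestamp")
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(t))
  structure(list(sensor_id = as.character(sensor_id), t = t, gyro = gyro,
                 accel = accel, mag = mag, rate_hz = rate_hz),
            class = "imu_series")
}

as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("'", what, "' must have 3 columns")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series '%s'>: %d samples, %.4g s at %.4g Hz nominal\n",
              x$sensor_id, length(x$t), diff(range(x$t)), x$rate_hz))
  invisible(x)
}

#' Construct an orientation time series
#'
#' @param sensor_id Character label.
#' @param t Numeric timestamps (seconds), strictly increasing.
#' @param q `n x 4` matrix of unit quaternions, scalar-first, sensor-to-earth.
#' @return An object of class `orientation_series`.
#' @export
orientation_series <- function(sensor_id, t, q) {
  t <- as.numeric(t)
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("'q' must have 4 columns (w, x, y, z)")
  if (nrow(q) != length(t)) stop("'q' must have one row per timestamp")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  storage.mode(q) <- "double"
  dimnames(q) <- NULL
  structure(list(sensor_id = as.character(sensor_id), t = t,
                 q = qmat_normalize(q)),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series '%s'>: %d samples over %.4g s\n",
              x$sensor_id, length(x$t), diff(range(x$t))))
  invisible(x)
}

#' Complementary-filter configuration
#'
#' @param algorithm One of `"madgwick"`, `"mahony"`, `"gyro_only"`.
#' @param beta Madgwick gain (dimensionless, >= 0).  The default 0.1 is the
#'   gain used at 100 Hz sampling; at 40 Hz a gain of 0.025 is appropriate.
#' @param kp,ki Mahony proportional and integral gains (>= 0).  `ki = 0`
#'   disables gyroscope-bias estimation.
#' @param mag_divisor Positive integer `m`: the magnetometer is incorporated
#'   only on every `m`-th filter update, which limits the influence of
#'   magnetically disturbed sensors (e.g. feet near in-ground ferromagnetics).
#' @param init_window_s Seconds of rest data averaged for the initial
#'   orientation (default 5, the length of the standing calibration pose).
#' @param use_mag Logical; set `FALSE` to ignore the magnetometer entirely
#'   (heading then relies on gyro integration alone).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(algorithm = c("madgwick", "mahony", "gyro_only"),
                          beta = 0.1, kp = 0.5, ki = 0, mag_divisor = 1L,
                          init_window_s = 5, use_mag = TRUE) {
  algorithm <- match.arg(algorithm)
  stopifnot(beta >= 0, kp >= 0, ki >= 0, mag_divisor >= 1, init_window_s >= 0)
  structure(list(algorithm = algorithm, beta = beta, kp = kp, ki = ki,
                 mag_divisor = as.integer(mag_divisor),
                 init_window_s = init_window_s, use_mag = isTRUE(use_mag)),
            class = "filter_config")
}

#' Initial orientation from rest accelerometer and magnetometer means
#'
#' TRIAD construction: the mean specific force defines earth +Z (up) and the
#' horizontal component of the mean magnetic field defines earth +X.
#'
#' @param accel_mean,mag_mean Length-3 mean accelerometer / magnetometer
#'   vectors over a rest window (sensor frame).
#' @return A unit quaternion (sensor-to-earth).
#' @export
initial_orientation <- function(accel_mean, mag_mean) {
  a <- as.numeric(accel_mean)
  m <- as.numeric(mag_mean)
  an <- sqrt(sum(a^2))
  if (an < 1e-9) stop("zero accelerometer mean: cannot determine the vertical")
  z <- a / an
  h <- m - sum(m * z) * z
  hn <- sqrt(sum(h^2))
  if (hn < 1e-9 * max(sqrt(sum(m^2)), 1e-12) || sqrt(sum(m^2)) < 1e-12)
    stop("magnetic field is (near-)parallel to gravity: heading is degenerate")
  x <- h / hn
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)  # rows: earth axes expressed in the sensor frame
  dimnames(R) <- NULL
  matrix_to_quat(R)
}

#' Single Madgwick filter update
#'
#' Gyro quaternion-derivative integration corrected by a normalised
#' gradient-descent step on the accelerometer (and, when `use_mag`,
#' magnetometer) objective, scaled by `beta`.  With `beta = 0` this is exact
#' one-step gyro integration.  A zero-norm accelerometer sample skips the
#' corrective step (gyro-only for that sample) with a warning.
#'
#' @param q Current unit quaternion (sensor-to-earth).
#' @param gyro,accel,mag Length-3 sample vectors (rad/s, m/s^2, any unit).
#' @param dt Timestep in seconds (> 0).
#' @param beta Filter gain.
#' @param use_mag Logical.
#' @return Updated unit quaternion.
#' @export
madgwick_step <- function(q, gyro, accel, mag, dt, beta = 0.1, use_mag = TRUE) {
  stopifnot(dt > 0)
  if (beta > 0 && sum(accel^2) == 0)
    warning("zero-norm accelerometer sample: corrective step skipped")
  madgwick_step_cpp(quat_normalize(q), as.numeric(gyro), as.numeric(accel),
                    as.numeric(mag), dt, beta, isTRUE(use_mag))
}

#' Single Mahony filter update
#'
#' Explicit complementary filter: proportional-integral feedback on the error
#' from cross products of measured vs predicted gravity (and magnetic field)
#' directions.  The integral term estimates the gyroscope bias; `kp = ki = 0`
#' reduces to pure gyro integration.
#'
#' @inheritParams madgwick_step
#' @param kp,ki Proportional and integral gains.
#' @param bias_state Length-3 current gyro-bias estimate (rad/s); start at
#'   zeros.
#' @return List with `q` (updated quaternion) and `bias_state` (updated
#'   gyro-bias estimate).
#' @export
mahony_step <- function(q, gyro, accel, mag, dt, kp = 0.5, ki = 0,
                        bias_state = c(0, 0, 0), use_mag = TRUE) {
  stopifnot(dt > 0)
  if ((kp > 0 || ki > 0) && sum(accel^2) == 0)
    warning("zero-norm accelerometer sample: corrective step skipped")
  out <- mahony_step_cpp(quat_normalize(q), as.numeric(gyro),
                         as.numeric(accel), as.numeric(mag), dt, kp, ki,
                         -as.numeric(bias_state), isTRUE(use_mag))
  list(q = out$q, bias_state = -out$integral)
}

#' Strap-down gyroscope integration
#'
#' Integrates angular velocity only (no accelerometer or magnetometer
#' correction), the baseline against which complementary-filter drift
#' rejection is judged.
#'
#' @param series An [imu_series].
#' @param q0 Initial unit quaternion (sensor-to-earth).
#' @return An [orientation_series] aligned to the input timestamps.
#' @export
integrate_gyro <- function(series, q0) {
  stopifnot(inherits(series, "imu_series"))
  Q <- gyro_filter_cpp(series$t, series$gyro, quat_normalize(q0), 0L)
  orientation_series(series$sensor_id, series$t, Q)
}

#' Run a sensor-fusion filter over an IMU series
#'
#' The first `init_window_s` seconds are used only to compute the initial
#' orientation from the mean accelerometer and magnetometer vectors (the
#' sensors are assumed at rest, e.g. during the standing calibration pose);
#' output samples in that window hold the initial orientation.  Timesteps are
#' taken per-sample from the timestamps, so dropped samples are handled
#' gracefully.
#'
#' @param series An [imu_series].
#' @param config A [filter_config].
#' @param q0 Optional explicit initial quaternion, bypassing rest
#'   initialisation (required if `init_window_s = 0`).
#' @return An [orientation_series] aligned to the input timestamps.
#' @export
run_filter <- function(series, config = filter_config(), q0 = NULL) {
  stopifnot(inherits(series, "imu_series"), inherits(config, "filter_config"))
  t <- series$t
  if (is.null(q0)) {
    if (config$init_window_s <= 0)
      stop("supply 'q0' when init_window_s is 0")
    in_win <- t <= t[1] + config$init_window_s
    n0 <- sum(in_win)
    if (t[length(t)] - t[1] < config$init_window_s || n0 < 2L)
      stop("series shorter than the initialisation window (",
           config$init_window_s, " s)")
    q0 <- initial_orientation(colMeans(series$accel[in_win, , drop = FALSE]),
                              colMeans(series$mag[in_win, , drop = FALSE]))
    start <- n0 - 1L  # 0-based index of the last init sample
  } else {
    q0 <- quat_normalize(q0)
    start <- 0L
  }
  if (config$algorithm != "gyro_only") {
    bad <- rowSums(series$accel^2) == 0
    if (any(bad))
      warning(sum(bad), " zero-norm accelerometer sample(s): corrective step",
              " skipped there")
  }
  Q <- switch(config$algorithm,
    madgwick = madgwick_filter_cpp(t, series$gyro, series$accel, series$mag,
                                   q0, config$beta, config$mag_divisor,
                                   config$use_mag, start),
    mahony = mahony_filter_cpp(t, series$gyro, series$accel, series$mag, q0,
                               config$kp, config$ki, config$mag_divisor,
                               config$use_mag, start)$q,
    gyro_only = gyro_filter_cpp(t, series$gyro, q0, start))
  orientation_series(series$sensor_id, t, Q)
}

#' Per-window RMS sensor-fusion error
#'
#' The orientation difference between an estimated and a reference orientation
#' series, expressed as the axis-angle rotation angle, summarised as the RMS
#' over consecutive windows (degrees).  A trailing partial window is dropped.
#'
#' @param est,ref [orientation_series] objects on identical timestamps.
#' @param window_s Window length in seconds (default 60).
#' @return Numeric vector of per-window RMS errors in degrees.
#' @export
fusion_error <- function(est, ref, window_s = 60) {
  stopifnot(inherits(est, "orientation_series"),
            inherits(ref, "orientation_series"))
  if (length(est$t) != length(ref$t) || max(abs(est$t - ref$t)) > 1e-9)
    stop("series are not time-aligned")
  ang <- rad2deg(qmat_angle(est$q, ref$q))
  window_rms(ang, est$t, window_s)
}

# RMS of x over complete windows of window_s seconds; partial tail dropped
window_rms <- function(x, t, window_s) {
  idx <- floor((t - t[1]) / window_s)
  nwin <- floor((t[length(t)] - t[1]) / window_s)
  if (nwin < 1) stop("series shorter than one window")
  out <- numeric(nwin)
  for (k in seq_len(nwin))
    out[k] <- sqrt(mean(x[idx == (k - 1)]^2))
  out
}

#' Resample an orientation series to new timestamps
#'
#' Spherical linear interpolation between bracketing samples; used to bring
#' sensors with disagreeing timestamps onto a common clock before inverse
#' kinematics.
#'
#' @param os An [orientation_series].
#' @param t_new New timestamps (within the original range).
#' @return An [orientation_series] on `t_new`.
#' @export
resample_orientations <- function(os, t_new) {
  stopifnot(inherits(os, "orientation_series"))
  t_new <- as.numeric(t_new)
  if (min(t_new) < os$t[1] - 1e-9 || max(t_new) > os$t[length(os$t)] + 1e-9)
    stop("t_new extends beyond the original series")
  i <- findInterval(t_new, os$t, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(os$t) - 1L)
  q1 <- os$q[i, , drop = FALSE]
  q2 <- os$q[i + 1L, , drop = FALSE]
  u <- (t_new - os$t[i]) / (os$t[i + 1L] - os$t[i])
  dot <- rowSums(q1 * q2)
  q2 <- q2 * ifelse(dot < 0, -1, 1)  # shortest arc
  dot <- abs(dot)
  om <- acos(pmin(1, dot))
  so <- sin(om)
  w1 <- ifelse(so < 1e-9, 1 - u, sin((1 - u) * om) / so)
  w2 <- ifelse(so < 1e-9, u, sin(u * om) / so)
  orientation_series(os$sensor_id, t_new, qmat_normalize(q1 * w1 + q2 * w2))
}
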