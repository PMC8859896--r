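# Synthetic-trial generator: ground-truth joint-angle trajectories and the
# corresponding noisy IMU signals, so the whole pipeline can be validated
# closed-loop.  Trials emulate the structure of the validation protocol the
# package targets: 8 sensors (upper back, lower back, bilateral thigh, shank,
# foot), a 5-s standing calibration window, then minutes of walking-and-
# turning or a repeated cycle of lower-extremity movements, sampled at 100 Hz
# (or 40 Hz).  Gait profiles are smooth sinusoid mixtures -- deliberately
# simple, band-limited and bounded, not biomechanically exact.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Trajectory generator configuration
#'
#' @param duration_s Trial length in seconds (including the calibration
#'   window).
#' @param rate_hz Sampling rate; 100 (default) or 40 mirror the study
#'   conditions, any positive value is accepted.
#' @param activity One of `"static_pose"`, `"walk"`, `"walk_turn"`,
#'   `"activity_cycle"`.
#' @param cadence_spm Gait cadence in steps per minute (two steps per stride).
#' @param amplitudes Named list overriding per-coordinate
#'   `c(offset, amplitude)` pairs in degrees (see `walk_profile()` in the
#'   package source for the defaults).
#' @param turn_interval_s,turn_angle_deg Heading-turn spacing and magnitude
#'   for `walk_turn` (alternating direction, smooth 2-s ramps).
#' @param calib_s Length of the initial all-zero standing calibration segment.
#' @param seed Integer seed (the trajectory itself is deterministic; the seed
#'   is recorded and threaded to downstream signal synthesis).
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(duration_s = 60, rate_hz = 100,
                              activity = c("walk", "walk_turn", "static_pose",
                                           "activity_cycle"),
                              cadence_spm = 100, amplitudes = list(),
                              turn_interval_s = 12, turn_angle_deg = 180,
                              calib_s = 5, seed = NULL) {
  activity <- match.arg(activity)
  stopifnot(duration_s > 0, rate_hz > 0, cadence_spm > 0, calib_s >= 0)
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 activity = activity, cadence_spm = cadence_spm,
                 amplitudes = amplitudes, turn_interval_s = turn_interval_s,
                 turn_angle_deg = turn_angle_deg, calib_s = calib_s,
                 seed = seed),
            class = "trajectory_config")
}

# default walk profile: offset, amplitude (deg), frequency multiple of the
# stride frequency, phase (rad); left-leg coordinates are the right ones
# phase-shifted by pi.
walk_profile <- function(amplitudes = list(), scale = 1) {
  def <- list(
    pelvis_tilt      = c(3, 2, 2, 0),
    pelvis_list      = c(0, 3, 1, 0),
    pelvis_rotation  = c(0, 5, 1, 0),
    lumbar_extension = c(-5, 2, 2, pi / 2),
    lumbar_bending   = c(0, 2, 1, pi),
    lumbar_rotation  = c(0, 4, 1, pi),
    hip_flexion      = c(8, 25, 1, 0),
    hip_adduction    = c(0, 5, 1, -pi / 2),
    hip_rotation     = c(0, 5, 1, pi / 3),
    knee_flexion     = c(30, 30, 1, -pi / 2),
    ankle_flexion    = c(0, 10, 1, pi))
  for (nm in names(amplitudes)) {
    v <- amplitudes[[nm]]
    if (!nm %in% names(def)) stop("unknown profile coordinate '", nm, "'")
    def[[nm]][seq_along(v)] <- v
  }
  if (scale != 1)
    def <- lapply(def, function(p) c(p[1] * scale, p[2] * scale, p[3:4]))
  def
}

# evaluate a profile at global times t (seconds), stride frequency f (Hz);
# returns an n x 19 matrix in DEGREES with the default-model coordinate names
eval_profile <- function(profile, t, f, cn) {
  q <- matrix(0, length(t), length(cn), dimnames = list(NULL, cn))
  for (nm in names(profile)) {
    p <- profile[[nm]]
    wave <- function(phase) p[1] + p[2] * sin(2 * pi * p[3] * f * t + phase)
    if (paste0(nm, "_r") %in% cn) {
      q[, paste0(nm, "_r")] <- wave(p[4])
      q[, paste0(nm, "_l")] <- wave(p[4] + pi)
    } else if (nm %in% cn) {
      q[, nm] <- wave(p[4])
    }
  }
  q
}

#' Generate a ground-truth joint-angle trajectory
#'
#' Every trial starts with a `calib_s`-second all-zero calibration segment
#' (the instructed neutral standing pose) and ramps smoothly into the
#' requested activity; all transitions are band-limited (1-s cross-fades), so
#' the implied angular velocities are finite.
#'
#' @param config A [trajectory_config].
#' @param model The [kinematic_model] whose coordinate bounds the trajectory
#'   must respect (default model if omitted).
#' @return A list of class `pose_trajectory`: `t` (seconds), `q` (frames x
#'   coordinates matrix, radians / metres), `labels` (activity label per
#'   sample), `config`.
#' @export
generate_trajectory <- function(config = trajectory_config(), model = NULL) {
  stopifnot(inherits(config, "trajectory_config"))
  if (is.null(model)) model <- build_default_model()
  cn <- coordinate_names(model)
  n <- round(config$duration_s * config$rate_hz)
  t <- (seq_len(n) - 1) / config$rate_hz
  f <- config$cadence_spm / 120  # strides per second
  prof_walk <- walk_profile(config$amplitudes)

  # activity segments: list(label, t0, t1, profile | function(t) -> matrix)
  t0 <- config$calib_s
  tend <- config$duration_s
  zero_fun <- function(tt) matrix(0, length(tt), length(cn),
                                  dimnames = list(NULL, cn))
  segs <- list(list(label = "calibration", t0 = 0, t1 = t0, fun = zero_fun))
  add_seg <- function(label, a, b, fun)
    segs[[length(segs) + 1L]] <<- list(label = label, t0 = a, t1 = b, fun = fun)
  prof_fun <- function(profile, freq) function(tt)
    eval_profile(profile, tt, freq, cn)

  if (config$activity == "static_pose") {
    add_seg("static_pose", t0, tend, zero_fun)
  } else if (config$activity %in% c("walk", "walk_turn")) {
    add_seg(config$activity, t0, tend, prof_fun(prof_walk, f))
  } else {  # activity_cycle: sit, stand, stairs, side-step, walk, run
    cyc <- list(
      list("sit", 6, function(tt) {
        q <- zero_fun(tt)
        q[, "hip_flexion_r"] <- q[, "hip_flexion_l"] <- 80
        q[, "knee_flexion_r"] <- q[, "knee_flexion_l"] <- 90
        q[, "ankle_flexion_r"] <- q[, "ankle_flexion_l"] <- 10
        q[, "lumbar_extension"] <- -10
        q
      }),
      list("stand", 4, zero_fun),
      list("stairs", 12, prof_fun(walk_profile(list(
        hip_flexion = c(20, 35), knee_flexion = c(45, 45),
        ankle_flexion = c(0, 15)), scale = 1), f * 0.7)),
      list("side_step", 8, prof_fun(walk_profile(list(
        hip_flexion = c(5, 5), hip_adduction = c(0, 18),
        knee_flexion = c(12, 10), ankle_flexion = c(0, 5))), f * 0.6)),
      list("walk", 15, prof_fun(prof_walk, f)),
      list("run", 10, prof_fun(walk_profile(config$amplitudes, scale = 1.3),
                               f * 1.5)))
    tt <- t0
    k <- 1L
    while (tt < tend) {
      s <- cyc[[(k - 1L) %% length(cyc) + 1L]]
      add_seg(s[[1]], tt, min(tt + s[[2]], tend), s[[3]])
      tt <- tt + s[[2]]
      k <- k + 1L
    }
  }

  # cross-fade into each segment over the first `ramp` seconds after its
  # start, so earlier segments (in particular the calibration window) are
  # never contaminated by what follows
  ramp <- 1
  starts <- vapply(segs, `[[`, numeric(1), "t0")
  seg_of <- findInterval(t, starts)
  qdeg <- matrix(0, n, length(cn), dimnames = list(NULL, cn))
  for (j in seq_along(segs)) {
    act <- which(seg_of == j | (j < length(segs) & seg_of == j + 1 &
                                  t < starts[pmin(j + 1, length(segs))] + ramp))
    if (!length(act)) next
    w <- rep(1, length(act))
    in_own <- seg_of[act] == j
    w[in_own] <- smoothstep((t[act][in_own] - segs[[j]]$t0) / ramp)
    if (j == 1L) w[in_own] <- 1  # first segment needs no fade-in
    w[!in_own] <- 1 - smoothstep(
      (t[act][!in_own] - starts[seg_of[act][!in_own]]) / ramp)
    qdeg[act, ] <- qdeg[act, ] + w * segs[[j]]$fun(t[act])
  }
  labels <- vapply(segs, `[[`, character(1), "label")[seg_of]

  if (config$activity == "walk_turn") {
    heading <- numeric(n)
    tk <- t0 + config$turn_interval_s
    sgn <- 1
    while (tk < tend) {
      heading <- heading + sgn * config$turn_angle_deg *
        smoothstep((t - tk) / 2)
      sgn <- -sgn
      tk <- tk + config$turn_interval_s
    }
    qdeg[, "pelvis_rotation"] <- qdeg[, "pelvis_rotation"] + heading
  }

  q <- qdeg
  rot <- !grepl("^pelvis_t[xyz]$", cn)
  q[, rot] <- deg2rad(qdeg[, rot])
  lo <- matrix(model$coords$lb, n, length(cn), byrow = TRUE)
  hi <- matrix(model$coords$ub, n, length(cn), byrow = TRUE)
  if (any(q < lo - 1e-9 | q > hi + 1e-9)) {
    bad <- cn[apply(q < lo - 1e-9 | q > hi + 1e-9, 2, any)]
    stop("trajectory exceeds model coordinate bounds: ",
         paste(bad, collapse = ", "))
  }
  structure(list(t = t, q = q, labels = labels, config = config),
            class = "pose_trajectory")
}

#' @export
print.pose_trajectory <- function(x, ...) {
  cat(sprintf("<pose_trajectory>: %s, %d frames at %g Hz (%.4g s)\n",
              x$config$activity, length(x$t), x$config$rate_hz,
              diff(range(x$t))))
  invisible(x)
}

#' IMU noise model
#'
#' Order-of-magnitude consumer-MEMS defaults; all standard deviations may be
#' set to zero for noiseless round trips.
#'
#' @param gyro_noise_density Gyro white noise, rad/s/sqrt(Hz) (scaled by
#'   `sqrt(rate/2)` to a per-sample standard deviation).
#' @param gyro_bias Constant gyro bias magnitude, rad/s per axis (each sensor
#'   draws a fixed bias vector with this per-axis RMS).
#' @param gyro_bias_rw Gyro bias random-walk density, rad/s/sqrt(s).
#' @param accel_noise Accelerometer white noise sd, m/s^2 per sample.
#' @param mag_noise_rel Magnetometer white noise, fraction of the field
#'   magnitude per sample.
#' @param mag_disturbance Optional list of disturbance events, each
#'   `list(sensor =, amp_deg =, t_on =, t_off =, ramp_s = 1)`: a smooth
#'   time-varying horizontal (about earth Z) rotation of the local field at
#'   one sensor, emulating ground-proximity ferromagnetic distortion.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(gyro_noise_density = 0.005, gyro_bias = 0.002,
                        gyro_bias_rw = 0, accel_noise = 0.05,
                        mag_noise_rel = 0.01, mag_disturbance = NULL) {
  stopifnot(gyro_noise_density >= 0, gyro_bias >= 0, gyro_bias_rw >= 0,
            accel_noise >= 0, mag_noise_rel >= 0)
  structure(list(gyro_noise_density = gyro_noise_density,
                 gyro_bias = gyro_bias, gyro_bias_rw = gyro_bias_rw,
                 accel_noise = accel_noise, mag_noise_rel = mag_noise_rel,
                 mag_disturbance = mag_disturbance),
            class = "noise_model")
}

#' Zero-noise model
#' @return A [noise_model] with every noise source off.
#' @export
noise_free <- function() noise_model(0, 0, 0, 0, 0, NULL)

#' Synthesise IMU signals from a ground-truth trajectory
#'
#' Realises the forward model the filters invert.  True sensor orientations
#' are `R_segment(q(t)) %*% R_offset`; gyro signals are sensor-frame angular
#' velocities from central differencing of the true orientations (one-sided at
#' the ends), plus bias and noise; accelerometers read specific force
#' (`gravity_only = TRUE`, the default, models a gravity-dominated
#' accelerometer; otherwise sensor-position linear acceleration from
#' double-differenced forward-kinematic positions is included); magnetometers
#' read the (optionally disturbed) earth field rotated into the sensor frame.
#'
#' @param model A [kinematic_model].
#' @param trajectory A [pose_trajectory].
#' @param offsets Named list of planted sensor-to-segment rotation matrices
#'   (default: identity for all IMU sites).
#' @param noise A [noise_model].
#' @param gravity Gravitational acceleration, m/s^2.
#' @param mag_field Earth magnetic field in the ground frame (any consistent
#'   unit; default has a realistic downward inclination).
#' @param gravity_only Logical (default TRUE): ignore linear acceleration in
#'   the accelerometer model.
#' @param mount_slip Optional `list(sensor =, angle_deg =, axis =, t_slip =,
#'   ramp_s = 0.3)`: rotates the named sensor on its segment mid-trial (a
#'   mounting slip), producing a stream whose calibrated offset is wrong from
#'   `t_slip` on -- the failure mode pre-screening is designed to catch.
#' @param seed Integer seed for all noise draws.
#' @return A list of class `synthetic_imu`: `imu` (named list of
#'   [imu_series]), `truth` (named list of [orientation_series]: the true
#'   sensor orientations, including any mount slip), `trajectory`, `offsets`,
#'   `mapping`, `params`.
#' @export
synthesize_imu <- function(model, trajectory, offsets = NULL,
                           noise = noise_model(), gravity = 9.81,
                           mag_field = c(0.4, 0, -0.3), gravity_only = TRUE,
                           mount_slip = NULL, seed = NULL) {
  stopifnot(inherits(model, "kinematic_model"),
            inherits(trajectory, "pose_trajectory"))
  mapping <- imu_sites(model)
  ids <- names(mapping)
  if (is.null(offsets))
    offsets <- stats::setNames(rep(list(diag(3)), length(ids)), ids)
  t <- trajectory$t
  n <- length(t)
  rate <- trajectory$config$rate_hz
  sa <- sensor_arrays(model, mapping, offsets)
  fk <- fk_sensors_cpp(model_arrays(model), sa$seg, sa$Roff, sa$spos,
                       trajectory$q)
  qs <- fk$q                     # 4 x K x n
  ps <- fk$pos                   # 3 x K x n
  gvec <- c(0, 0, -gravity)

  with_seed(seed, {
    out <- list()
    truth <- list()
    for (k in seq_along(ids)) {
      id <- ids[k]
      Q <- t(qs[, k, ])          # n x 4 true sensor orientation
      if (!is.null(mount_slip) && identical(mount_slip$sensor, id)) {
        s <- smoothstep((t - mount_slip$t_slip) /
                          max(mount_slip$ramp_s %||% 0.3, 1e-6))
        ax <- mount_slip$axis / sqrt(sum(mount_slip$axis^2))
        ang <- deg2rad(mount_slip$angle_deg) * s
        slip <- cbind(cos(ang / 2), sin(ang / 2) %o% ax)
        Q <- qmat_multiply(Q, slip)   # slip in the sensor frame
      }
      Q <- qmat_normalize(Q)

      # angular velocity from orientation differencing (body frame)
      gyro <- matrix(0, n, 3)
      rel <- qmat_multiply(qmat_conjugate(Q[1:(n - 2), , drop = FALSE]),
                           Q[3:n, , drop = FALSE])
      gyro[2:(n - 1), ] <- qmat_logvee(rel) / (t[3:n] - t[1:(n - 2)])
      rel1 <- qmat_multiply(qmat_conjugate(Q[1, , drop = FALSE]),
                            Q[2, , drop = FALSE])
      gyro[1, ] <- qmat_logvee(rel1) / (t[2] - t[1])
      reln <- qmat_multiply(qmat_conjugate(Q[n - 1, , drop = FALSE]),
                            Q[n, , drop = FALSE])
      gyro[n, ] <- qmat_logvee(reln) / (t[n] - t[n - 1])

      # specific force
      if (gravity_only) {
        lin <- matrix(0, n, 3)
      } else {
        P <- t(ps[, k, ])
        lin <- matrix(0, n, 3)
        dt2 <- (diff(t)[-1] + diff(t)[-(n - 1)]) / 2
        lin[2:(n - 1), ] <- (P[3:n, ] - 2 * P[2:(n - 1), ] +
                               P[1:(n - 2), ]) / dt2^2
      }
      spec <- lin - matrix(gvec, n, 3, byrow = TRUE)
      accel <- qmat_rotate(qmat_conjugate(Q), spec)

      # magnetometer, with optional per-sensor field disturbance
      field <- matrix(mag_field, n, 3, byrow = TRUE)
      for (d in noise$mag_disturbance) {
        if (!identical(d$sensor, id)) next
        ramp <- max(d$ramp_s %||% 1, 1e-6)
        ang <- deg2rad(d$amp_deg) *
          (smoothstep((t - d$t_on) / ramp) - smoothstep((t - d$t_off) / ramp))
        ca <- cos(ang); sn <- sin(ang)
        field <- cbind(ca * field[, 1] - sn * field[, 2],
                       sn * field[, 1] + ca * field[, 2], field[, 3])
      }
      mag <- qmat_rotate(qmat_conjugate(Q), field)

      # noise injection
      if (noise$gyro_bias > 0) {
        u <- stats::rnorm(3)
        bias <- noise$gyro_bias * sqrt(3) * u / sqrt(sum(u^2))
        gyro <- gyro + matrix(bias, n, 3, byrow = TRUE)
      }
      if (noise$gyro_bias_rw > 0) {
        dt <- c(0, diff(t))
        rw <- apply(matrix(stats::rnorm(3 * n), n, 3) *
                      noise$gyro_bias_rw * sqrt(dt), 2, cumsum)
        gyro <- gyro + rw
      }
      if (noise$gyro_noise_density > 0)
        gyro <- gyro + matrix(stats::rnorm(3 * n), n, 3) *
          (noise$gyro_noise_density * sqrt(rate / 2))
      if (noise$accel_noise > 0)
        accel <- accel + matrix(stats::rnorm(3 * n), n, 3) * noise$accel_noise
      if (noise$mag_noise_rel > 0)
        mag <- mag + matrix(stats::rnorm(3 * n), n, 3) *
          (noise$mag_noise_rel * sqrt(sum(mag_field^2)))

      out[[id]] <- imu_series(id, t, gyro, accel, mag, rate_hz = rate)
      truth[[id]] <- orientation_series(id, t, Q)
    }
    structure(list(imu = out, truth = truth, trajectory = trajectory,
                   offsets = offsets, mapping = mapping,
                   params = list(noise = noise, gravity = gravity,
                                 mag_field = mag_field,
                                 gravity_only = gravity_only,
                                 mount_slip = mount_slip, seed = seed)),
              class = "synthetic_imu")
  })
}

#' @export
print.synthetic_imu <- function(x, ...) {
  cat(sprintf("<synthetic_imu>: %d sensors, %d frames (%s)\n",
              length(x$imu), length(x$trajectory$t),
              x$trajectory$config$activity))
  invisible(x)
}

#' Random sensor-to-segment mounting offsets
#'
#' @param ids Sensor ids.
#' @param angle_range_deg Offset magnitude range (default 5--25 degrees).
#' @param seed Integer seed.
#' @return Named list of rotation matrices.
#' @export
random_offsets <- function(ids, angle_range_deg = c(5, 25), seed = NULL) {
  with_seed(seed, {
    out <- lapply(ids, function(id) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      quat_to_matrix(axis_angle_to_quat(
        u, deg2rad(stats::runif(1, angle_range_deg[1], angle_range_deg[2]))))
    })
    stats::setNames(out, ids)
  })
}

#' Generate a study-structured synthetic fixture
#'
#' Builds the full closed-loop test article: the default 8-sensor model with
#' distinct planted mounting offsets, a walking-and-turning trial and
#' (optionally) a movement-cycle trial with consumer-MEMS noise and a
#' magnetic disturbance on the foot sensors (starting after the screening
#' window), plus a deliberately corrupted variant of the walking trial in
#' which the right-foot sensor slips 60 degrees on its mount just after
#' calibration -- the stream the pre-screening rules are designed to exclude.
#'
#' @param seed Integer seed driving offsets and all noise.
#' @param duration_s Trial length (default 600 s, the study's 10-min trials).
#' @param rate_hz Sampling rate (100 or 40).
#' @param include_activity Also generate the movement-cycle trial.
#' @param noise A [noise_model] for the trial signals (foot-sensor magnetic
#'   disturbances are added on top).
#' @return A list of class `study_fixture`: `model`, `offsets`, `walking`,
#'   `corrupted`, optionally `activity`, and `seed`.
#' @export
make_study_fixture <- function(seed = 1, duration_s = 600, rate_hz = 100,
                               include_activity = FALSE,
                               noise = noise_model()) {
  model <- build_default_model()
  ids <- names(imu_sites(model))
  offsets <- random_offsets(ids, seed = seed)
  dist <- list(
    list(sensor = "foot_r_imu", amp_deg = 20, t_on = 15,
         t_off = duration_s - 5, ramp_s = 2),
    list(sensor = "foot_l_imu", amp_deg = -15, t_on = 20,
         t_off = duration_s - 5, ramp_s = 2))
  noise_d <- noise
  noise_d$mag_disturbance <- c(noise$mag_disturbance, dist)
  walk_cfg <- trajectory_config(duration_s = duration_s, rate_hz = rate_hz,
                                activity = "walk_turn", seed = seed)
  walk_traj <- generate_trajectory(walk_cfg, model)
  walking <- synthesize_imu(model, walk_traj, offsets, noise_d,
                            seed = seed + 1L)
  corrupted <- synthesize_imu(model, walk_traj, offsets, noise_d,
                              mount_slip = list(sensor = "foot_r_imu",
                                                angle_deg = 60,
                                                axis = c(1, 0.3, 0),
                                                t_slip = 5.2, ramp_s = 0.3),
                              seed = seed + 2L)
  out <- list(model = model, offsets = offsets, walking = walking,
              corrupted = corrupted, seed = seed)
  if (include_activity) {
    act_cfg <- trajectory_config(duration_s = duration_s, rate_hz = rate_hz,
                                 activity = "activity_cycle", seed = seed)
    out$activity <- synthesize_imu(model, generate_trajectory(act_cfg, model),
                                   offsets, noise_d, seed = seed + 3L)
  }
  class(out) <- "study_fixture"
  out
}
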