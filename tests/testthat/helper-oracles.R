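# Independent oracles, written against definitions (not against the package's
# implementation paths), plus shared fixtures cached across test files.

# random unit quaternion (uniform-ish via normalised Gaussian)
rand_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# oracle: quaternion -> rotation matrix via Rodrigues on the extracted
# axis-angle (independent of the component formula in the package)
oracle_quat2mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-15) return(diag(3))
  u <- q[2:4] / vn
  th <- 2 * atan2(vn, q[1])
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# oracle: forward kinematics by composing per-joint quaternions
oracle_fk_quat <- function(model, pose) {
  q <- imukin:::as_pose(model, pose)
  euler_zxy_quat <- function(a) {
    qz <- c(cos(a[1] / 2), 0, 0, sin(a[1] / 2))
    qx <- c(cos(a[2] / 2), sin(a[2] / 2), 0, 0)
    qy <- c(cos(a[3] / 2), 0, sin(a[3] / 2), 0)
    quat_multiply(quat_multiply(qz, qx), qy)
  }
  out <- list()
  for (s in model$segments) {
    qj <- switch(s$joint$type,
      weld0 = c(1, 0, 0, 0),
      pin1 = axis_angle_to_quat(s$joint$axis, q[[s$joint$coords[1]]]),
      euler_zxy_quat(unname(q[s$joint$coords[1:3]])))
    qfix <- matrix_to_quat(s$Rfix)
    loc <- quat_multiply(qfix, qj)
    out[[s$name]] <- if (is.na(s$parent)) loc else
      quat_multiply(out[[s$parent]], loc)
  }
  out
}

# oracle: ordinary least squares via explicit normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# oracle: Pearson correlation from its definition
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# per-row angle between two quaternion matrices (independent small helper)
quat_angle_rows <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    orientation_difference(A[i, ], B[i, ]), numeric(1))
}

# random in-bounds pose, limited to +/- max_deg on the free coordinates
rand_pose <- function(model, max_deg = 30) {
  q <- default_pose(model)
  free <- model$coords$free
  lo <- pmax(model$coords$lb[free], -max_deg * pi / 180)
  hi <- pmin(model$coords$ub[free], max_deg * pi / 180)
  q[model$coords$name[free]] <- stats::runif(sum(free), lo, hi)
  q
}

# ---- shared fixtures (built once per test run) -----------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# zero-noise 20-s walking trial with planted offsets, fused and calibrated
walk_fixture <- function() {
  cached("walk20", {
    model <- build_default_model()
    traj <- generate_trajectory(
      trajectory_config(duration_s = 20, rate_hz = 100, activity = "walk"),
      model)
    offsets <- random_offsets(names(imukin:::imu_sites(model)), seed = 101)
    sim <- synthesize_imu(model, traj, offsets, noise_free(), seed = 102)
    orientations <- lapply(sim$imu, run_filter,
                           config = filter_config("madgwick", beta = 0.1))
    measured <- lapply(orientations, average_orientation, window = c(0, 5))
    registration <- calibrate(model, measured)
    list(model = model, traj = traj, offsets = offsets, sim = sim,
         orientations = orientations, registration = registration)
  })
}

# truth coordinates in degrees (rotations) for comparison with imu_ik output
truth_degrees <- function(traj) {
  out <- traj$q
  rot <- !grepl("^pelvis_t[xyz]$", colnames(out))
  out[, rot] <- out[, rot] * 180 / pi
  out
}

# single-pin-joint toy model: fixed base welded to the ground carrying one
# moving segment; `sensors` ids all attach to the moving segment
pin_model <- function(axis = c(0, 0, 1)) {
  segs <- list(
    list(name = "base", parent = NA_character_,
         joint = list(name = "ground", type = "weld0", axis = c(0, 0, 1),
                      coords = character(0)),
         tfix = c(0, 0, 0), Rfix = diag(3), length = 0.1,
         imu = list(id = "base_imu", pos = c(0, 0, 0))),
    list(name = "arm", parent = "base",
         joint = list(name = "hinge", type = "pin1", axis = axis,
                      coords = "hinge_angle"),
         tfix = c(0, 0.1, 0), Rfix = diag(3), length = 0.3,
         imu = list(id = "arm_imu", pos = c(0, 0.2, 0))))
  coords <- data.frame(name = "hinge_angle", lb = -pi, ub = pi, free = TRUE,
                       stringsAsFactors = FALSE)
  kinematic_model(segs, coords)
}
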