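# Orientation-tracking inverse kinematics: per frame, find the joint angles q
# minimising  sum_i w_i * theta_i^2,  where theta_i is the axis-angle rotation
# angle between the measured sensor orientation and the model's virtual IMU
# orientation (radians inside the objective, degrees in all reports).
# Pelvis translations are frozen; coordinates are clamped to their bounds;
# each frame is warm-started from the previous solution.

#' IK solver control parameters
#'
#' @param max_iter Maximum Levenberg--Marquardt iterations per frame.
#' @param cost_tol Relative cost-decrease convergence tolerance.
#' @param step_tol Parameter-step convergence tolerance (radians).
#' @param lambda0 Initial LM damping.
#' @param fd_h Finite-difference step for the residual Jacobian (radians).
#' @return A list of class `ik_control`.
#' @export
ik_control <- function(max_iter = 200L, cost_tol = 1e-9, step_tol = 1e-11,
                       lambda0 = 1e-3, fd_h = 1e-7) {
  structure(list(max_iter = as.integer(max_iter), cost_tol = cost_tol,
                 step_tol = step_tol, lambda0 = lambda0, fd_h = fd_h),
            class = "ik_control")
}

#' Default sensor weights with distal downweighting
#'
#' Sensors closest to the ground are most exposed to ferromagnetic
#' disturbance, so their orientation terms are downweighted: 1.0 for torso,
#' pelvis and thigh sensors, 0.5 for shanks, 0.25 for feet.
#'
#' @param registration A [sensor_registration] (the weights are keyed by its
#'   sensor ids and assigned by host segment).
#' @param shank,foot Weights for shank- and foot-mounted sensors.
#' @return Named numeric vector of weights.
#' @export
default_ik_weights <- function(registration, shank = 0.5, foot = 0.25) {
  segs <- unlist(registration$mapping)
  w <- rep(1, length(segs))
  w[grepl("^tibia", segs)] <- shank
  w[grepl("^foot", segs)] <- foot
  stats::setNames(w, names(segs))
}

check_weights <- function(weights, ids) {
  if (is.null(names(weights)))
    stop("'weights' must be a named vector (sensor_id -> weight)")
  w <- stats::setNames(rep(0, length(ids)), ids)
  known <- intersect(names(weights), ids)
  w[known] <- weights[known]
  if (any(w < 0)) stop("weights must be >= 0")
  if (all(w == 0)) stop("at least one sensor must have positive weight")
  w
}

#' Weighted orientation-tracking cost
#'
#' Pure function returning `sum_i w_i * theta_i^2` with `theta_i` in radians:
#' the objective the IK solver minimises.  Implemented via the R-level
#' rotation algebra, independently of the compiled solver path.
#'
#' @param model A [kinematic_model].
#' @param registration A [sensor_registration].
#' @param measured Named list of measured unit quaternions.
#' @param weights Named weights (see [default_ik_weights()]).
#' @param pose Coordinate vector.
#' @return Scalar cost (radians squared).
#' @export
ik_cost <- function(model, registration, measured, weights, pose) {
  vir <- virtual_imu_orientations(model, pose, registration)
  ids <- intersect(names(registration$mapping), names(measured))
  w <- check_weights(weights, names(registration$mapping))
  total <- 0
  for (id in ids) {
    th <- rotation_angle(relative_rotation(
      quat_to_matrix(quat_normalize(as.numeric(measured[[id]]))), vir[[id]]))
    total <- total + w[[id]] * th^2
  }
  total
}

ik_prepare <- function(model, registration, weights) {
  sa <- sensor_arrays(model, unlist(registration$mapping),
                      registration$offsets)
  w <- check_weights(weights, sa$ids)
  free <- which(model$coords$free) - 1L
  list(ma = model_arrays(model), sa = sa, w = unname(w[sa$ids]),
       free = free,
       lb = model$coords$lb[model$coords$free],
       ub = model$coords$ub[model$coords$free])
}

#' Solve inverse kinematics for a single frame
#'
#' @param model A [kinematic_model].
#' @param registration A [sensor_registration].
#' @param measured Named list of measured unit quaternions (sensors missing
#'   from the list are dropped for the frame).
#' @param weights Named sensor weights; default [default_ik_weights()].
#' @param q_init Starting pose (default: neutral).
#' @param control An [ik_control].
#' @return List with `pose` (named coordinate vector), `theta` (named
#'   per-sensor orientation differences, degrees), `cost` (radians squared),
#'   `iterations` and `converged`.
#' @export
ik_frame <- function(model, registration, measured,
                     weights = default_ik_weights(registration),
                     q_init = NULL, control = ik_control()) {
  prep <- ik_prepare(model, registration, weights)
  q0 <- if (is.null(q_init)) default_pose(model) else as_pose(model, q_init)
  K <- length(prep$sa$ids)
  qm <- array(NA_real_, c(4, K, 1))
  for (k in seq_len(K)) {
    id <- prep$sa$ids[k]
    if (id %in% names(measured))
      qm[, k, 1] <- quat_normalize(as.numeric(measured[[id]]))
  }
  sol <- ik_solve_cpp(prep$ma, prep$sa$seg, prep$sa$Roff, qm, prep$w, q0,
                      prep$free, prep$lb, prep$ub, unclass(control))
  list(pose = stats::setNames(drop(sol$q), coordinate_names(model)),
       theta = stats::setNames(rad2deg(drop(sol$theta)), prep$sa$ids),
       cost = sol$cost[1], iterations = sol$iterations[1],
       converged = sol$converged[1])
}

#' Fit joint-angle trajectories by orientation-tracking inverse kinematics
#'
#' The central fitting function: for every frame, solves the weighted
#' least-squares orientation-tracking problem over the model's free
#' coordinates (pelvis translations frozen, coordinates clamped to bounds),
#' warm-starting each frame from the previous solution.  Sensors absent from
#' a frame (NA quaternion) have their term dropped for that frame.
#'
#' @param model A [kinematic_model].
#' @param registration A [sensor_registration].
#' @param orientations Named list of [orientation_series], one per sensor,
#'   sharing identical timestamps (resample upstream with
#'   [resample_orientations()] if needed).
#' @param weights Named sensor weights; default [default_ik_weights()].
#' @param q0 Pose used to warm-start the first frame (default: neutral).
#' @param control An [ik_control].
#' @return An object of class `imu_ik` with components `time`, `coordinates`
#'   (frames x coordinates matrix, degrees for rotations, metres for
#'   translations), `theta` (frames x sensors orientation differences,
#'   degrees), `cost` (per-frame objective, radians squared), `iterations`,
#'   `converged`, plus the model, registration and weights used.  Methods:
#'   `print`, `summary`, `coef`, `residuals`, `plot`, `as.data.frame`.
#' @export
ik_trajectory <- function(model, registration, orientations,
                          weights = default_ik_weights(registration),
                          q0 = NULL, control = ik_control()) {
  stopifnot(inherits(model, "kinematic_model"),
            inherits(registration, "sensor_registration"))
  prep <- ik_prepare(model, registration, weights)
  ids <- prep$sa$ids
  present <- intersect(ids, names(orientations))
  if (!length(present)) stop("no registered sensor has an orientation series")
  tref <- orientations[[present[1]]]$t
  for (id in present) {
    os <- orientations[[id]]
    if (!inherits(os, "orientation_series"))
      stop("orientations[['", id, "']] is not an orientation_series")
    if (length(os$t) != length(tref) || max(abs(os$t - tref)) > 1e-9)
      stop("orientation series do not share timestamps; resample first")
  }
  n <- length(tref)
  qm <- array(NA_real_, c(4, length(ids), n))
  for (k in seq_along(ids))
    if (ids[k] %in% present)
      qm[, k, ] <- t(orientations[[ids[k]]]$q)
  qinit <- if (is.null(q0)) default_pose(model) else as_pose(model, q0)
  sol <- ik_solve_cpp(prep$ma, prep$sa$seg, prep$sa$Roff, qm, prep$w, qinit,
                      prep$free, prep$lb, prep$ub, unclass(control))
  cn <- coordinate_names(model)
  coords <- sol$q
  rot <- !grepl("^pelvis_t[xyz]$", cn)
  coords[, rot] <- rad2deg(coords[, rot])
  colnames(coords) <- cn
  theta <- rad2deg(sol$theta)
  colnames(theta) <- ids
  structure(list(time = tref, coordinates = coords, theta = theta,
                 cost = sol$cost, iterations = sol$iterations,
                 converged = sol$converged, model = model,
                 registration = registration,
                 weights = check_weights(weights, ids),
                 control = control, call = match.call()),
            class = "imu_ik")
}
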