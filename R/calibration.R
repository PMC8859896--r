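# Sensor-to-segment calibration: fixed rotational offsets computed from fused
# sensor orientations while the subject holds a known (by default neutral)
# calibration pose.

#' Average a window of orientations
#'
#' Sign-aligned normalised quaternion mean: every sample is aligned to the
#' hemisphere of the first (the double cover makes `q` and `-q` the same
#' rotation), averaged componentwise and renormalised.  The maximum
#' within-window orientation difference to the mean is attached as attribute
#' `"dispersion"` (radians); a dispersion above `max_dispersion_deg` raises a
#' warning (or an error if `on_unstable = "error"`).
#'
#' @param q `n x 4` quaternion matrix, or an [orientation_series] (optionally
#'   restricted by `window`).
#' @param window Optional length-2 time window (seconds) when `q` is an
#'   [orientation_series].
#' @param max_dispersion_deg Dispersion threshold in degrees (default 10).
#' @param on_unstable `"warning"` (default) or `"error"`.
#' @return Unit quaternion with attribute `dispersion`.
#' @export
average_orientation <- function(q, window = NULL, max_dispersion_deg = 10,
                                on_unstable = c("warning", "error")) {
  on_unstable <- match.arg(on_unstable)
  if (inherits(q, "orientation_series")) {
    keep <- if (is.null(window)) rep(TRUE, length(q$t)) else
      q$t >= window[1] & q$t <= window[2]
    q <- q$q[keep, , drop = FALSE]
  }
  q <- as.matrix(q)
  if (nrow(q) < 1L) stop("empty orientation window")
  q <- qmat_normalize(q)
  sgn <- ifelse(q %*% q[1, ] < 0, -1, 1)
  q <- q * as.vector(sgn)
  m <- quat_normalize(colMeans(q))
  disp <- max(qmat_angle(q, matrix(m, nrow(q), 4, byrow = TRUE)))
  if (rad2deg(disp) > max_dispersion_deg) {
    msg <- sprintf(
      "unstable calibration window: orientation dispersion %.1f deg > %.1f deg",
      rad2deg(disp), max_dispersion_deg)
    if (on_unstable == "error") stop(msg) else warning(msg)
  }
  attr(m, "dispersion") <- disp
  m
}

#' Register sensors to model segments from a calibration pose
#'
#' With the model posed at `q_cal` (default: the all-zero neutral standing
#' pose), each sensor's fixed rotational offset is
#' `R_offset = t(R_segment(q_cal)) %*% R_measured`, so that the virtual IMU
#' orientations at `q_cal` reproduce the measured orientations exactly.
#'
#' @param model A [kinematic_model].
#' @param measured Named list (or `n x 4` one-row matrix list) of measured
#'   unit quaternions, one per sensor — typically [average_orientation()] of
#'   the fused estimates over the calibration window.
#' @param mapping Named character vector `sensor_id -> segment name`; default
#'   is the model's built-in IMU sites.
#' @param q_cal Calibration pose (named coordinate vector, radians); default
#'   all-zero.  An externally supplied pose reproduces protocols where the
#'   calibration posture was measured independently.
#' @param window Optional length-2 numeric, the time window the measured
#'   orientations were averaged over (metadata only).
#' @return An object of class `sensor_registration`.
#' @export
calibrate <- function(model, measured, mapping = NULL, q_cal = NULL,
                      window = NULL) {
  stopifnot(inherits(model, "kinematic_model"))
  if (is.null(mapping)) mapping <- imu_sites(model)
  mapping <- unlist(mapping)
  missing_ids <- setdiff(names(mapping), names(measured))
  if (length(missing_ids))
    stop("sensor(s) missing from 'measured': ",
         paste(missing_ids, collapse = ", "))
  q_cal <- if (is.null(q_cal)) default_pose(model) else as_pose(model, q_cal)
  fk <- fk_orient_cpp(model_arrays(model), matrix(q_cal, nrow = 1))
  dim(fk) <- c(3, 3, length(model$segments))
  seg_or <- lapply(seq_along(model$segments), function(i) fk[, , i])
  names(seg_or) <- names(model$segments)
  offsets <- list()
  meas_q <- list()
  for (id in names(mapping)) {
    seg <- mapping[[id]]
    if (!seg %in% names(model$segments))
      stop("sensor '", id, "' mapped to unknown segment '", seg, "'")
    qm <- quat_normalize(as.numeric(measured[[id]]))
    offsets[[id]] <- t(seg_or[[seg]]) %*% quat_to_matrix(qm)
    meas_q[[id]] <- qm
  }
  structure(list(mapping = as.list(mapping), offsets = offsets,
                 q_cal = q_cal, measured = meas_q,
                 seg_orientations = seg_or[unlist(mapping)],
                 window = window),
            class = "sensor_registration")
}

#' @export
print.sensor_registration <- function(x, ...) {
  cat("<sensor_registration>:", length(x$mapping), "sensors\n")
  for (id in names(x$mapping)) {
    ang <- rad2deg(rotation_angle(x$offsets[[id]]))
    cat(sprintf("  %-14s -> %-10s offset %6.1f deg\n", id, x$mapping[[id]], ang))
  }
  invisible(x)
}

#' Align per-sensor headings to a reference sensor
#'
#' Magnetic disturbance mostly corrupts heading (rotation about the vertical),
#' and per-sensor heading disagreement at calibration injects constant axial
#' joint-angle bias.  This correction computes, for each sensor, the Z-twist
#' (swing--twist decomposition about earth Z) of the discrepancy between the
#' supplied measured orientation and the registered virtual orientation at the
#' calibration pose, and rotates the sensor's offset about earth Z so its
#' heading discrepancy matches the reference sensor's.  Inclination is
#' untouched, so a tilt disturbance is deliberately not removed.  Off by
#' default in the pipeline.
#'
#' @param registration A [sensor_registration].
#' @param reference_sensor Sensor id whose heading is trusted.
#' @param measured Named list of measured quaternions at the calibration pose;
#'   defaults to the ones stored at calibration (in which case the
#'   registration is returned unchanged, as all discrepancies are zero by
#'   construction).
#' @return The adjusted [sensor_registration].
#' @export
heading_align <- function(registration, reference_sensor, measured = NULL) {
  stopifnot(inherits(registration, "sensor_registration"))
  if (!reference_sensor %in% names(registration$mapping))
    stop("reference sensor '", reference_sensor, "' not in registration")
  if (is.null(measured)) measured <- registration$measured
  if (!reference_sensor %in% names(measured))
    stop("reference sensor '", reference_sensor, "' missing from 'measured'")
  twist <- function(id) {
    S <- registration$seg_orientations[[registration$mapping[[id]]]]
    V <- S %*% registration$offsets[[id]]
    M <- quat_to_matrix(quat_normalize(as.numeric(measured[[id]])))
    heading_twist(M %*% t(V))
  }
  d_ref <- twist(reference_sensor)
  for (id in intersect(names(registration$mapping), names(measured))) {
    d <- twist(id) - d_ref
    S <- registration$seg_orientations[[registration$mapping[[id]]]]
    registration$offsets[[id]] <- t(S) %*% rot_z(d) %*% S %*%
      registration$offsets[[id]]
  }
  registration
}

#' Save or load a sensor registration
#'
#' YAML (or JSON, by file extension) with the sensor-to-segment map, offset
#' quaternions and calibration pose; round-trip stable.
#'
#' @param registration A [sensor_registration].
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `load_registration` returns a [sensor_registration]; `save_...`
#'   returns `path` invisibly.
#' @export
save_registration <- function(registration, path) {
  doc <- list(
    mapping = registration$mapping,
    offsets = lapply(registration$offsets,
                     function(R) as.numeric(matrix_to_quat(R))),
    q_cal = as.list(registration$q_cal),
    measured = lapply(registration$measured, as.numeric),
    seg_orientations = lapply(registration$seg_orientations,
                              function(R) as.numeric(matrix_to_quat(R))),
    window = registration$window)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname save_registration
#' @export
load_registration <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  structure(list(
    mapping = as.list(unlist(doc$mapping)),
    offsets = lapply(doc$offsets, function(q) quat_to_matrix(as.numeric(q))),
    q_cal = unlist(doc$q_cal),
    measured = lapply(doc$measured, as.numeric),
    seg_orientations = lapply(doc$seg_orientations,
                              function(q) quat_to_matrix(as.numeric(q))),
    window = doc$window),
    class = "sensor_registration")
}
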