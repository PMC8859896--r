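# Kinematic-chain skeletal model: a tree of segments rooted at the pelvis,
# joints of type free6 / ball3 / pin1 / weld0, virtual IMU sites, and forward
# kinematics from a joint-coordinate vector q.
#
# Segment-frame convention at the neutral (all-zero) pose: X forward, Y up,
# Z to the subject's right.  Ball joints use intrinsic Z-X-Y Euler angles
# mapped to (flexion, adduction, rotation) — flexion about Z (mediolateral
# axis), adduction about X (anteroposterior), axial rotation about Y
# (longitudinal).  The ground frame is the fusion earth frame (Z up, X =
# magnetic north at initialisation); the root segment's fixed offset aligns
# the two.

# ground alignment of the segment convention frame:
# columns = segment axes (X fwd, Y up, Z right) expressed in ground coords
R_SEG2GROUND <- matrix(c(1, 0, 0,
                         0, 0, -1,
                         0, 1, 0), 3, 3, byrow = TRUE)

JOINT_TYPES <- c("free6", "ball3", "pin1", "weld0")

#' Build the default lower-body + torso kinematic model
#'
#' Pelvis root with 6 degrees of freedom (3 rotations tilt/list/rotation + 3
#' translations, translations frozen during IK), a 3-dof ball joint to the
#' torso (carrying the upper-back IMU), and per leg a 3-dof ball hip
#' (flexion/adduction/rotation), a 1-dof pin knee and a 1-dof pin ankle
#' (plantarflexion--dorsiflexion; subtalar and toe joints welded): 19
#' coordinates in total.  Eight virtual IMU sites are attached: upper back
#' (torso), lower back (pelvis) and bilateral thigh, shank and foot.
#'
#' @param hip_range,knee_range,ankle_range Physiologic coordinate bounds in
#'   degrees: hip applies to flexion (adduction and rotation use +/-60),
#'   knee and ankle to their single dof.
#' @return An object of class `kinematic_model`.
#' @export
build_default_model <- function(hip_range = c(-120, 120),
                                knee_range = c(0, 140),
                                ankle_range = c(-60, 60)) {
  seg <- function(name, parent, jname, jtype, coords, tfix, Rfix = diag(3),
                  axis = c(0, 0, 1), length = 0, imu = NULL)
    list(name = name, parent = parent,
         joint = list(name = jname, type = jtype, axis = axis, coords = coords),
         tfix = tfix, Rfix = Rfix, length = length, imu = imu)

  hip_lb <- deg2rad(hip_range[1]); hip_ub <- deg2rad(hip_range[2])
  knee_lb <- deg2rad(knee_range[1]); knee_ub <- deg2rad(knee_range[2])
  ank_lb <- deg2rad(ankle_range[1]); ank_ub <- deg2rad(ankle_range[2])

  segments <- list(
    seg("pelvis", NA_character_, "ground_pelvis", "free6",
        c("pelvis_tilt", "pelvis_list", "pelvis_rotation",
          "pelvis_tx", "pelvis_ty", "pelvis_tz"),
        tfix = c(0, 0, 0.95), Rfix = R_SEG2GROUND, length = 0.15,
        imu = list(id = "pelvis_imu", pos = c(-0.10, 0.05, 0))),
    seg("torso", "pelvis", "back", "ball3",
        c("lumbar_extension", "lumbar_bending", "lumbar_rotation"),
        tfix = c(0, 0.10, 0), length = 0.45,
        imu = list(id = "torso_imu", pos = c(-0.08, 0.35, 0))),
    seg("femur_r", "pelvis", "hip_r", "ball3",
        c("hip_flexion_r", "hip_adduction_r", "hip_rotation_r"),
        tfix = c(0, -0.07, 0.084), length = 0.40,
        imu = list(id = "thigh_r_imu", pos = c(0, -0.20, 0.07))),
    seg("tibia_r", "femur_r", "knee_r", "pin1", "knee_flexion_r",
        tfix = c(0, -0.40, 0), length = 0.43,
        imu = list(id = "shank_r_imu", pos = c(0, -0.22, 0.05))),
    seg("foot_r", "tibia_r", "ankle_r", "pin1", "ankle_flexion_r",
        tfix = c(0, -0.43, 0), length = 0.20,
        imu = list(id = "foot_r_imu", pos = c(0.10, -0.03, 0))),
    seg("femur_l", "pelvis", "hip_l", "ball3",
        c("hip_flexion_l", "hip_adduction_l", "hip_rotation_l"),
        tfix = c(0, -0.07, -0.084), length = 0.40,
        imu = list(id = "thigh_l_imu", pos = c(0, -0.20, -0.07))),
    seg("tibia_l", "femur_l", "knee_l", "pin1", "knee_flexion_l",
        tfix = c(0, -0.40, 0), length = 0.43,
        imu = list(id = "shank_l_imu", pos = c(0, -0.22, -0.05))),
    seg("foot_l", "tibia_l", "ankle_l", "pin1", "ankle_flexion_l",
        tfix = c(0, -0.43, 0), length = 0.20,
        imu = list(id = "foot_l_imu", pos = c(0.10, -0.03, 0))))

  co <- function(name, lb, ub, free = TRUE)
    data.frame(name = name, lb = lb, ub = ub, free = free,
               stringsAsFactors = FALSE)
  pr <- deg2rad(360)
  coords <- rbind(
    co("pelvis_tilt", -pr, pr), co("pelvis_list", -pr, pr),
    co("pelvis_rotation", -2 * pr, 2 * pr),
    co("pelvis_tx", -5, 5, FALSE), co("pelvis_ty", -5, 5, FALSE),
    co("pelvis_tz", -5, 5, FALSE),
    co("lumbar_extension", -pi / 2, pi / 2),
    co("lumbar_bending", -pi / 2, pi / 2),
    co("lumbar_rotation", -pi / 2, pi / 2),
    co("hip_flexion_r", hip_lb, hip_ub),
    co("hip_adduction_r", -pi / 3, pi / 3),
    co("hip_rotation_r", -pi / 3, pi / 3),
    co("knee_flexion_r", knee_lb, knee_ub),
    co("ankle_flexion_r", ank_lb, ank_ub),
    co("hip_flexion_l", hip_lb, hip_ub),
    co("hip_adduction_l", -pi / 3, pi / 3),
    co("hip_rotation_l", -pi / 3, pi / 3),
    co("knee_flexion_l", knee_lb, knee_ub),
    co("ankle_flexion_l", ank_lb, ank_ub))

  kinematic_model(segments, coords)
}

#' Construct a kinematic model
#'
#' Lower-level constructor; most users want [build_default_model()].
#' Validates that the segments form a tree with a single root, that joint
#' types are known, and that coordinate counts match joint types (free6: 6,
#' ball3: 3, pin1: 1, weld0: 0).
#'
#' @param segments List of segment descriptions (see [build_default_model()]
#'   source for the layout).
#' @param coords Data frame with columns `name`, `lb`, `ub`, `free`.
#' @return An object of class `kinematic_model`.
#' @export
kinematic_model <- function(segments, coords) {
  names(segments) <- vapply(segments, `[[`, "", "name")
  for (s in segments) {
    jt <- s$joint$type
    if (!jt %in% JOINT_TYPES)
      stop("segment '", s$name, "': unknown joint type '", jt, "'")
    need <- c(free6 = 6L, ball3 = 3L, pin1 = 1L, weld0 = 0L)[[jt]]
    if (length(s$joint$coords) != need)
      stop("segment '", s$name, "': joint type ", jt, " needs ", need,
           " coordinate(s), got ", length(s$joint$coords))
    if (!is.na(s$parent) && !s$parent %in% names(segments))
      stop("segment '", s$name, "': unknown parent '", s$parent, "'")
  }
  roots <- names(segments)[vapply(segments, function(s) is.na(s$parent), TRUE)]
  if (length(roots) != 1L)
    stop("model must have exactly one root segment, found: ",
         paste(roots, collapse = ", "))
  # topological order + cycle check
  order <- roots
  remaining <- setdiff(names(segments), roots)
  repeat {
    nxt <- remaining[vapply(segments[remaining],
                            function(s) s$parent %in% order, TRUE)]
    if (!length(nxt)) break
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  if (length(remaining))
    stop("segment graph contains a cycle or unreachable segments: ",
         paste(remaining, collapse = ", "))
  segments <- segments[order]
  all_co <- unlist(lapply(segments, function(s) s$joint$coords))
  if (anyDuplicated(all_co)) stop("duplicated coordinate names")
  if (!setequal(all_co, coords$name))
    stop("coordinate table does not match joint coordinates")
  coords <- coords[match(unname(all_co), coords$name), , drop = FALSE]
  rownames(coords) <- NULL
  structure(list(segments = segments, coords = coords, root = roots),
            class = "kinematic_model")
}

#' @export
print.kinematic_model <- function(x, ...) {
  cat(sprintf("<kinematic_model>: %d segments, %d coordinates (%d free), root '%s'\n",
              length(x$segments), nrow(x$coords), sum(x$coords$free), x$root))
  imus <- imu_sites(x)
  cat("  IMU sites:", paste(names(imus), collapse = ", "), "\n")
  invisible(x)
}

#' Model coordinate names
#' @param model A [kinematic_model].
#' @return Character vector in q-vector order.
#' @export
coordinate_names <- function(model) model$coords$name

#' The neutral (all-zero) pose
#' @param model A [kinematic_model].
#' @return Named numeric vector of coordinate values (radians; metres for
#'   pelvis translations), all zero: the instructed standing calibration pose.
#' @export
default_pose <- function(model) {
  stats::setNames(numeric(nrow(model$coords)), model$coords$name)
}

#' IMU sites defined by a model
#' @param model A [kinematic_model].
#' @return Named character vector mapping sensor id to host segment name.
#' @export
imu_sites <- function(model) {
  out <- character(0)
  for (s in model$segments)
    if (!is.null(s$imu)) out[s$imu$id] <- s$name
  out
}

as_pose <- function(model, pose) {
  cn <- coordinate_names(model)
  if (is.null(names(pose))) {
    if (length(pose) != length(cn))
      stop("pose length ", length(pose), " does not match the model's ",
           length(cn), " coordinates")
    return(stats::setNames(as.numeric(pose), cn))
  }
  q <- default_pose(model)
  unknown <- setdiff(names(pose), cn)
  if (length(unknown))
    stop("unknown coordinate(s): ", paste(unknown, collapse = ", "))
  q[names(pose)] <- as.numeric(pose)
  q
}

# Flatten a model for the C++ kernels (see src/imukin.cpp for the layout).
model_arrays <- function(model) {
  segs <- model$segments
  S <- length(segs)
  cn <- coordinate_names(model)
  parent <- integer(S)
  jtype <- integer(S)
  qidx <- matrix(-1L, 3, S)
  axis <- matrix(0, 3, S)
  Rfix <- array(0, c(3, 3, S))
  tfix <- matrix(0, 3, S)
  tidx <- rep(-1L, 3)
  for (i in seq_len(S)) {
    s <- segs[[i]]
    parent[i] <- if (is.na(s$parent)) -1L else match(s$parent, names(segs)) - 1L
    jtype[i] <- switch(s$joint$type, weld0 = 0L, pin1 = 1L, ball3 = 2L,
                       free6 = 2L)
    ci <- match(s$joint$coords, cn) - 1L
    if (s$joint$type == "pin1") {
      qidx[1, i] <- ci[1]
      ax <- s$joint$axis
      axis[, i] <- ax / sqrt(sum(ax^2))
    } else if (s$joint$type %in% c("ball3", "free6")) {
      qidx[, i] <- ci[1:3]
      if (s$joint$type == "free6") tidx <- as.integer(ci[4:6])
    }
    Rfix[, , i] <- s$Rfix
    tfix[, i] <- s$tfix
  }
  list(parent = parent, jtype = jtype, qidx = qidx, axis = axis,
       Rfix = Rfix, tfix = tfix, tidx = tidx)
}

sensor_arrays <- function(model, mapping, offsets = NULL) {
  segs <- names(model$segments)
  ids <- names(mapping)
  bad <- !unname(mapping) %in% segs
  if (any(bad))
    stop("sensor(s) mapped to unknown segment(s): ",
         paste(sprintf("%s -> %s", ids[bad], mapping[bad]), collapse = ", "))
  K <- length(ids)
  Roff <- array(0, c(3, 3, K))
  spos <- matrix(0, 3, K)
  for (k in seq_len(K)) {
    Roff[, , k] <- if (is.null(offsets)) diag(3) else offsets[[ids[k]]]
    s <- model$segments[[mapping[[ids[k]]]]]
    spos[, k] <- if (!is.null(s$imu) && s$imu$id == ids[k]) s$imu$pos else c(0, 0, 0)
  }
  list(ids = ids, seg = match(unname(mapping), segs) - 1L, Roff = Roff,
       spos = spos)
}

#' Forward kinematics
#'
#' Computes each segment's ground-frame orientation (product of ancestor fixed
#' offsets and joint rotations, root first) and position (using the model's
#' nominal joint-centre offsets; positions feed the synthetic-signal
#' generator, not IK).
#'
#' @param model A [kinematic_model].
#' @param pose Named (or full-length) coordinate vector, radians / metres.
#' @return List with `orientation` (named list of 3x3 matrices) and
#'   `position` (named list of length-3 vectors).
#' @export
forward_kinematics <- function(model, pose) {
  q <- as_pose(model, pose)
  oob <- q < model$coords$lb - 1e-9 | q > model$coords$ub + 1e-9
  if (any(oob))
    warning("coordinate(s) out of bounds: ",
            paste(names(q)[oob], collapse = ", "))
  ma <- model_arrays(model)
  R <- fk_orient_cpp(ma, matrix(q, nrow = 1))
  dim(R) <- c(3, 3, length(model$segments))
  pos <- fk_positions(model, q)
  orientation <- lapply(seq_along(model$segments), function(i) R[, , i])
  names(orientation) <- names(model$segments)
  list(orientation = orientation, position = pos)
}

# R-side segment positions (small n use only)
fk_positions <- function(model, q) {
  segs <- model$segments
  fk <- fk_orient_cpp(model_arrays(model), matrix(q, nrow = 1))
  dim(fk) <- c(3, 3, length(segs))
  pos <- list()
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (is.na(s$parent)) {
      tr <- s$tfix
      ti <- match(s$joint$coords[4:6], coordinate_names(model))
      if (s$joint$type == "free6") tr <- tr + q[ti]
      pos[[s$name]] <- unname(tr)
    } else {
      pos[[s$name]] <- pos[[s$parent]] +
        drop(fk[, , match(s$parent, names(segs))] %*% s$tfix)
    }
  }
  pos
}

#' Virtual IMU orientations
#'
#' The model-predicted orientation of each registered sensor:
#' `R_segment(q) %*% R_offset`, the quantity the inverse-kinematics tracker
#' matches against the measured sensor orientations.
#'
#' @param model A [kinematic_model].
#' @param pose Coordinate vector.
#' @param registration A [sensor_registration].
#' @return Named list of 3x3 rotation matrices, one per registered sensor.
#' @export
virtual_imu_orientations <- function(model, pose, registration) {
  stopifnot(inherits(registration, "sensor_registration"))
  q <- as_pose(model, pose)
  fk <- fk_orient_cpp(model_arrays(model), matrix(q, nrow = 1))
  dim(fk) <- c(3, 3, length(model$segments))
  out <- lapply(names(registration$mapping), function(id) {
    seg <- registration$mapping[[id]]
    if (!seg %in% names(model$segments))
      stop("sensor '", id, "' mapped to unknown segment '", seg, "'")
    fk[, , match(seg, names(model$segments))] %*% registration$offsets[[id]]
  })
  names(out) <- names(registration$mapping)
  out
}

#' Save or load a kinematic model as YAML
#'
#' The on-disk schema stores segments (parent, joint type, axis, coordinate
#' names, fixed offsets with rotations as scalar-first quaternions, nominal
#' lengths, IMU sites) and the coordinate table; the round trip is lossless.
#'
#' @param model A [kinematic_model].
#' @param path File path.
#' @return `load_model` returns a [kinematic_model]; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  segs <- lapply(model$segments, function(s) {
    out <- list(name = s$name,
                parent = if (is.na(s$parent)) NULL else s$parent,
                joint = list(name = s$joint$name, type = s$joint$type,
                             axis = as.numeric(s$joint$axis),
                             coords = as.list(s$joint$coords)),
                tfix = as.numeric(s$tfix),
                Rfix_quat = as.numeric(matrix_to_quat(s$Rfix)),
                length = s$length)
    if (!is.null(s$imu))
      out$imu <- list(id = s$imu$id, pos = as.numeric(s$imu$pos))
    out
  })
  coords <- lapply(seq_len(nrow(model$coords)), function(i)
    list(name = model$coords$name[i], lb = model$coords$lb[i],
         ub = model$coords$ub[i], free = model$coords$free[i]))
  yaml::write_yaml(list(segments = unname(segs), coordinates = coords), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$segments) || is.null(doc$coordinates))
    stop("model config '", path, "': missing 'segments' or 'coordinates'")
  segs <- lapply(doc$segments, function(s) {
    for (f in c("name", "joint", "tfix", "Rfix_quat"))
      if (is.null(s[[f]]))
        stop("model config: segment missing field '", f, "'")
    if (is.null(s$joint$type) || !s$joint$type %in% JOINT_TYPES)
      stop("model config: segment '", s$name, "': unknown joint type '",
           s$joint$type, "' in field 'joint.type'")
    list(name = s$name,
         parent = if (is.null(s$parent)) NA_character_ else s$parent,
         joint = list(name = s$joint$name, type = s$joint$type,
                      axis = as.numeric(s$joint$axis %||% c(0, 0, 1)),
                      coords = unlist(s$joint$coords) %||% character(0)),
         tfix = as.numeric(s$tfix),
         Rfix = quat_to_matrix(as.numeric(s$Rfix_quat)),
         length = s$length %||% 0,
         imu = if (is.null(s$imu)) NULL else
           list(id = s$imu$id, pos = as.numeric(s$imu$pos)))
  })
  coords <- do.call(rbind, lapply(doc$coordinates, function(co)
    data.frame(name = co$name, lb = co$lb, ub = co$ub,
               free = isTRUE(co$free), stringsAsFactors = FALSE)))
  kinematic_model(segs, coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
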