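# Exact 3-D rotation algebra.  Quaternions are length-4 numeric vectors in
# scalar-first order (w, x, y, z); rotation matrices are 3x3 with R^T R = I and
# det(R) = +1.  All angles are radians internally; file and report I/O uses
# degrees.

#' Normalise a quaternion
#'
#' @param q Numeric length-4 quaternion, scalar-first `(w, x, y, z)`.
#' @return A unit quaternion.
#' @export
quat_normalize <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n < .Machine$double.eps)
    stop("quaternion has zero (or non-finite) norm")
  q / n
}

#' Quaternion product
#'
#' Hamilton product `a %*% b`; composing rotations so that rotating by the
#' result equals rotating first by `b`, then by `a`.
#'
#' @param a,b Quaternions `(w, x, y, z)`.
#' @return The product quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quat_multiply
#' @param q Quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotate a 3-vector by a quaternion
#'
#' @param q Unit quaternion (renormalised internally).
#' @param v Numeric length-3 vector.
#' @return The rotated vector `R(q) v`.
#' @export
quat_rotate <- function(q, v) {
  drop(quat_to_matrix(q) %*% as.numeric(v))
}

#' Convert a quaternion to a rotation matrix
#'
#' @param q Quaternion `(w, x, y, z)`; renormalised internally, an all-zero
#'   quaternion is an error.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a quaternion
#'
#' Uses Shepperd-style branch selection for numerical stability in every trace
#' regime, and returns the representative with `w >= 0` (the quaternion double
#' cover means `q` and `-q` are the same rotation).
#'
#' @param R 3x3 rotation matrix, orthonormal within `tol`.
#' @param tol Orthonormality tolerance (default `1e-6`).
#' @return Unit quaternion `(w, x, y, z)` with `w >= 0`.
#' @export
matrix_to_quat <- function(R, tol = 1e-6) {
  check_rotation_matrix(R, tol)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

check_rotation_matrix <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)))
    stop("expected a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("matrix is not orthonormal within tolerance ", tol)
  if (det(R) < 0)
    stop("matrix has determinant -1 (reflection, not a rotation)")
  invisible(R)
}

#' Relative rotation between two orientations
#'
#' Returns `t(Ra) %*% Rb`, the rotation carrying orientation `Ra` onto `Rb`.
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return 3x3 rotation matrix.
#' @export
relative_rotation <- function(Ra, Rb) {
  check_rotation_matrix(Ra)
  check_rotation_matrix(Rb)
  t(Ra) %*% Rb
}

#' Rotation angle of a rotation matrix
#'
#' The angle of the axis-angle representation,
#' `acos((tr(R) - 1) / 2)`, with the arccos argument clamped to `[-1, 1]` so
#' floating-point round-off never produces `NaN`.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  check_rotation_matrix(R)
  arg <- (R[1, 1] + R[2, 2] + R[3, 3] - 1) / 2
  acos(min(1, max(-1, arg)))
}

#' Orientation difference between two quaternions
#'
#' The angle of the axis-angle representation of the relative rotation between
#' two orientations: the standard scalar distance on SO(3).  Symmetric in its
#' arguments and invariant to the quaternion double cover (`q` and `-q`
#' compare equal).
#'
#' @param qa,qb Quaternions `(w, x, y, z)`.
#' @return Angle in radians, in `[0, pi]`.
#' @export
orientation_difference <- function(qa, qb) {
  qa <- quat_normalize(qa)
  qb <- quat_normalize(qb)
  r <- quat_multiply(quat_conjugate(qa), qb)
  # atan2 form: numerically stable near 0 and pi, unlike acos of the dot
  2 * atan2(sqrt(sum(r[2:4]^2)), abs(r[1]))
}

#' Axis-angle construction and extraction
#'
#' @param axis Length-3 rotation axis (normalised internally; must be
#'   non-zero when `angle != 0`).
#' @param angle Rotation angle in radians.
#' @return `axis_angle_to_quat`: a unit quaternion. `quat_to_axis_angle`: a
#'   list with `axis` (unit 3-vector, `(1, 0, 0)` by convention for the
#'   identity) and `angle` in `[0, pi]`.
#' @export
axis_angle_to_quat <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) {
    if (abs(angle) < .Machine$double.eps) return(c(1, 0, 0, 0))
    stop("zero axis with non-zero angle")
  }
  quat_normalize(c(cos(angle / 2), sin(angle / 2) * axis / n))
}

#' @rdname axis_angle_to_quat
#' @param q Unit quaternion.
#' @export
quat_to_axis_angle <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-12) return(list(axis = c(1, 0, 0), angle = 0))
  list(axis = q[2:4] / vn, angle = 2 * atan2(vn, q[1]))
}

# single-axis rotation matrices (radians)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Z-twist (heading component) of a rotation, via swing-twist decomposition
# about the earth Z axis.  Returns radians in (-pi, pi].
heading_twist <- function(R) {
  q <- matrix_to_quat(R)
  2 * atan2(q[4], q[1])
}

# --- vectorised quaternion helpers on n x 4 matrices (rows = quaternions) ---

qmat_normalize <- function(Q) Q / sqrt(rowSums(Q^2))

qmat_multiply <- function(A, B) {
  cbind(A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
        A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
        A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
        A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1])
}

qmat_conjugate <- function(Q) cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])

# rotate rows of V (n x 3) by rows of Q (n x 4)
qmat_rotate <- function(Q, V) {
  P <- qmat_multiply(qmat_multiply(Q, cbind(0, V)), qmat_conjugate(Q))
  P[, 2:4, drop = FALSE]
}

# per-row angle between two quaternion series, radians (stable atan2 form)
qmat_angle <- function(A, B) {
  R <- qmat_multiply(qmat_conjugate(qmat_normalize(A)), qmat_normalize(B))
  2 * atan2(sqrt(rowSums(R[, 2:4, drop = FALSE]^2)), abs(R[, 1]))
}

# rotation vector (axis * angle) per row, radians
qmat_logvee <- function(Q) {
  Q <- qmat_normalize(Q)
  sgn <- ifelse(Q[, 1] < 0, -1, 1)
  Q <- Q * sgn
  vn <- sqrt(rowSums(Q[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, Q[, 1])
  scl <- ifelse(vn < 1e-14, 2, ang / pmax(vn, 1e-300))
  Q[, 2:4, drop = FALSE] * scl
}
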