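# S3 methods for the fitted orientation-tracking IK object.

#' @export
print.imu_ik <- function(x, ...) {
  cat(sprintf("<imu_ik>: %d frames over %.4g s, %d sensors, %d coordinates\n",
              length(x$time), diff(range(x$time)), ncol(x$theta),
              ncol(x$coordinates)))
  cat(sprintf("  converged frames: %d/%d; mean IK orientation difference: %.2f deg\n",
              sum(x$converged), length(x$time),
              mean(x$theta, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.imu_ik <- function(object, ...) object$coordinates

#' Per-sensor IK orientation differences
#'
#' The per-frame angles `theta_i` (degrees) between measured and virtual IMU
#' orientations at the solution: the fit residuals, used for drift monitoring
#' and sensor pre-screening.
#'
#' @param object An `imu_ik` fit.
#' @param ... Unused.
#' @return Frames x sensors numeric matrix, degrees.
#' @export
residuals.imu_ik <- function(object, ...) object$theta

#' @export
as.data.frame.imu_ik <- function(x, ...) {
  data.frame(time = x$time, x$coordinates, check.names = FALSE)
}

#' Summarise an orientation-tracking IK fit
#'
#' @param object An `imu_ik` fit.
#' @param ... Unused.
#' @return A list of class `summary.imu_ik`: per-coordinate range, per-sensor
#'   RMS orientation difference (degrees) and solver diagnostics.
#' @export
summary.imu_ik <- function(object, ...) {
  rot <- !grepl("^pelvis_t[xyz]$", colnames(object$coordinates))
  co <- object$coordinates[, rot, drop = FALSE]
  coord_tab <- data.frame(
    coordinate = colnames(co),
    min = apply(co, 2, min), max = apply(co, 2, max),
    mean = colMeans(co), row.names = NULL)
  theta_rms <- sqrt(colMeans(object$theta^2, na.rm = TRUE))
  out <- list(
    n_frames = length(object$time),
    duration_s = diff(range(object$time)),
    coordinates = coord_tab,
    theta_rms_deg = theta_rms,
    weights = object$weights,
    converged = sum(object$converged),
    mean_iterations = mean(object$iterations),
    mean_cost = mean(object$cost))
  class(out) <- "summary.imu_ik"
  out
}

#' @export
print.summary.imu_ik <- function(x, ...) {
  cat(sprintf("Orientation-tracking IK fit: %d frames, %.4g s\n",
              x$n_frames, x$duration_s))
  cat(sprintf("Converged: %d/%d frames (mean %.1f LM iterations, mean cost %.3g rad^2)\n",
              x$converged, x$n_frames, x$mean_iterations, x$mean_cost))
  cat("\nJoint coordinates (deg):\n")
  print(x$coordinates, digits = 3)
  cat("\nIK orientation differences, RMS per sensor (deg):\n")
  tab <- data.frame(sensor = names(x$theta_rms_deg),
                    weight = unname(x$weights[names(x$theta_rms_deg)]),
                    rms_deg = unname(x$theta_rms_deg), row.names = NULL)
  print(tab, digits = 3)
  invisible(x)
}

#' Plot joint-angle trajectories or IK residuals
#'
#' @param x An `imu_ik` fit.
#' @param which Coordinate names to plot (default: right-side sagittal
#'   angles), or `"theta"` for per-sensor orientation differences.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.imu_ik <- function(x, which = NULL, ...) {
  if (identical(which, "theta")) {
    graphics::matplot(x$time, x$theta, type = "l", lty = 1,
                      xlab = "time (s)",
                      ylab = "IK orientation difference (deg)", ...)
    graphics::legend("topright", colnames(x$theta), col = seq_len(ncol(x$theta)),
                     lty = 1, cex = 0.7, bty = "n")
    return(invisible(x))
  }
  if (is.null(which))
    which <- intersect(c("hip_flexion_r", "knee_flexion_r", "ankle_flexion_r",
                         "pelvis_tilt"), colnames(x$coordinates))
  graphics::matplot(x$time, x$coordinates[, which, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "angle (deg)", ...)
  graphics::legend("topright", which, col = seq_along(which), lty = 1,
                   cex = 0.7, bty = "n")
  invisible(x)
}
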