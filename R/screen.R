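# Rule-based pre-screening of sensor streams using early-trial IK orientation
# differences.  Two rules, applied to the first window of a trial:
#   (i)  absolute: any theta sample exceeds 45 degrees, indicating poor
#        orientation tracking;
#   (ii) range: the average range of theta over 60-ms bins exceeds 30 degrees,
#        indicating unrealistic variability.
# A sensor is included iff neither rule fires; thresholds are strict
# inequalities, so a sensor sitting exactly at a threshold is included.

#' Screening configuration
#'
#' @param window_s Seconds of the trial inspected (default 10).
#' @param abs_threshold_deg Absolute-difference threshold (default 45).
#' @param bin_ms Bin width for the range rule, milliseconds (default 60).
#' @param range_threshold_deg Mean bin-range threshold (default 30).
#' @param abs_statistic `"max"` (default) or `"mean"`: how the absolute rule
#'   summarises theta over the window before comparison.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(window_s = 10, abs_threshold_deg = 45, bin_ms = 60,
                          range_threshold_deg = 30,
                          abs_statistic = c("max", "mean")) {
  stopifnot(window_s > 0, abs_threshold_deg > 0, bin_ms > 0,
            range_threshold_deg > 0)
  structure(list(window_s = window_s, abs_threshold_deg = abs_threshold_deg,
                 bin_ms = bin_ms, range_threshold_deg = range_threshold_deg,
                 abs_statistic = match.arg(abs_statistic)),
            class = "screen_config")
}

#' Screen sensors on their IK orientation differences
#'
#' @param theta Matrix (frames x sensors, named columns) or named list of
#'   numeric vectors: per-sensor IK orientation differences in degrees,
#'   covering at least `window_s` seconds at `rate_hz`.
#' @param rate_hz Sampling rate of the theta series.
#' @param config A [screen_config].
#' @return A data frame of class `screen_report` with one row per sensor:
#'   `sensor`, `included`, `rule` (`"none"`, `"absolute"`, `"range"` or
#'   `"both"`), `max_theta_deg` (or mean, per `abs_statistic`) and
#'   `mean_bin_range_deg`.
#' @export
screen_sensors <- function(theta, rate_hz, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (is.list(theta) && !is.data.frame(theta))
    theta <- do.call(cbind, theta)
  theta <- as.matrix(theta)
  if (is.null(colnames(theta))) stop("'theta' needs sensor names")
  nwin <- floor(config$window_s * rate_hz)
  if (nrow(theta) < nwin)
    stop("theta series (", nrow(theta), " samples) shorter than the ",
         config$window_s, " s screening window at ", rate_hz, " Hz")
  th <- theta[seq_len(nwin), , drop = FALSE]
  nb <- round(config$bin_ms * rate_hz / 1000)
  if (nb < 2L) {
    warning("bin of <2 samples at ", rate_hz, " Hz; bin size floored at 2")
    nb <- 2L
  }
  nbins <- floor(nwin / nb)  # final partial bin dropped
  bin_of <- rep(seq_len(nbins), each = nb)
  rows <- lapply(colnames(th), function(id) {
    x <- th[, id]
    absstat <- if (config$abs_statistic == "max") max(x) else mean(x)
    xb <- x[seq_len(nbins * nb)]
    rng <- tapply(xb, bin_of, function(v) max(v) - min(v))
    mbr <- mean(rng)
    fired_abs <- absstat > config$abs_threshold_deg
    fired_rng <- mbr > config$range_threshold_deg
    rule <- if (fired_abs && fired_rng) "both" else if (fired_abs) "absolute"
      else if (fired_rng) "range" else "none"
    data.frame(sensor = id, included = rule == "none", rule = rule,
               max_theta_deg = absstat, mean_bin_range_deg = mbr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_report", "data.frame")
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Sensor pre-screening report\n")
  df <- as.data.frame(x)
  df$max_theta_deg <- round(df$max_theta_deg, 2)
  df$mean_bin_range_deg <- round(df$mean_bin_range_deg, 2)
  print.data.frame(df, row.names = FALSE)
  n_ex <- sum(!x$included)
  cat(if (n_ex) sprintf("%d sensor(s) excluded\n", n_ex) else
    "all sensors included\n")
  invisible(x)
}

#' Pre-screen a trial's sensors via an early IK pass
#'
#' Runs orientation-tracking IK over the first `window_s` seconds with all
#' sensors at their configured weights, extracts the per-sensor orientation
#' differences and applies [screen_sensors()].  The recommended workflow is
#' screen, drop excluded sensors (set their weight to zero), then re-run IK on
#' the full trial.
#'
#' @param model A [kinematic_model].
#' @param registration A [sensor_registration].
#' @param orientations Named list of [orientation_series].
#' @param weights Named sensor weights.
#' @param config A [screen_config].
#' @param control An [ik_control].
#' @return A `screen_report` with the screening IK fit attached as attribute
#'   `"ik"`.
#' @export
screen_trial <- function(model, registration, orientations,
                         weights = default_ik_weights(registration),
                         config = screen_config(), control = ik_control()) {
  tref <- orientations[[1]]$t
  rate <- 1 / stats::median(diff(tref))
  keep <- tref <= tref[1] + config$window_s
  if (tref[length(tref)] - tref[1] < config$window_s)
    stop("trial shorter than the ", config$window_s, " s screening window")
  head_or <- lapply(orientations, function(os)
    orientation_series(os$sensor_id, os$t[keep], os$q[keep, , drop = FALSE]))
  fit <- ik_trajectory(model, registration, head_or, weights,
                       control = control)
  rep <- screen_sensors(residuals(fit), rate, config)
  attr(rep, "ik") <- fit
  rep
}

#' Apply a screening report to a weight vector
#'
#' @param weights Named sensor weights.
#' @param report A `screen_report`.
#' @return The weights with excluded sensors set to 0.
#' @export
apply_screen <- function(weights, report) {
  excluded <- report$sensor[!report$included]
  weights[names(weights) %in% excluded] <- 0
  weights
}
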