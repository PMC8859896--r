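# Agreement and drift statistics: per-window RMS differences, OLS drift
# slopes of per-minute RMS, Pearson correlations, cross-correlation
# synchronisation, and median/IQR summaries with 1.5*IQR outlier flagging.
# Angle differences are wrapped to (-180, 180] degrees before squaring (gait
# angles live far from +/-180, so this is a safety net, not a semantic
# change).

wrap_angle <- function(d) {
  x <- d %% 360
  x[x > 180] <- x[x > 180] - 360
  x
}

#' Per-window RMS difference between two angle series
#'
#' @param a,b Numeric angle series in degrees, identical timestamps.
#' @param t Shared timestamps, seconds.
#' @param window_s Window length (default 60 s, i.e. per-minute RMS).  A
#'   trailing partial window is dropped.
#' @return Numeric vector of per-window RMS differences, degrees.
#' @export
rms_per_window <- function(a, b, t, window_s = 60) {
  if (length(a) != length(b) || length(a) != length(t))
    stop("'a', 'b' and 't' must have equal length")
  window_rms(wrap_angle(a - b), t, window_s)
}

#' Drift fit: linear regression of per-minute RMS differences on time
#'
#' Ordinary least squares with intercept, fit with [stats::lm()].  A slope
#' near zero indicates no accumulation of error over the trial.
#'
#' @param per_minute_rms Numeric vector of per-minute RMS values (degrees).
#' @param minutes Minute indices (default `1, 2, ...`).
#' @return A list of class `drift_fit`: `slope` (deg/min), `intercept` (deg)
#'   and `r_squared`.
#' @export
drift_fit <- function(per_minute_rms, minutes = seq_along(per_minute_rms)) {
  if (length(per_minute_rms) < 2L)
    stop("drift fit needs at least 2 per-minute values")
  if (length(minutes) != length(per_minute_rms))
    stop("'minutes' and 'per_minute_rms' must have equal length")
  fit <- stats::lm(per_minute_rms ~ minutes)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((per_minute_rms - mean(per_minute_rms))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("drift: %.3f deg/min (intercept %.2f deg, r^2 %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Pearson correlation between two angle series
#'
#' @param a,b Numeric series of equal length; both must be non-constant (a
#'   zero-variance input is an explicit error, not a silent `NA`).
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance in input")
  stats::cor(a, b)
}

#' Synchronise two series by cross-correlation
#'
#' Finds the integer-sample lag maximising the normalised cross-correlation of
#' the mean-removed series, within `max_lag_s`.  Ties are broken toward the
#' smallest absolute lag.  The returned lag is positive when `b` lags `a`
#' (i.e. `b(t) ~ a(t - lag)`).
#'
#' @param a,b Numeric series on a common sampling clock.
#' @param rate_hz Sampling rate.
#' @param max_lag_s Maximum lag searched, seconds.
#' @return Lag in seconds, with attributes `lag_samples` and `correlation`.
#'   A boundary lag triggers a low-confidence warning.
#' @export
synchronize_series <- function(a, b, rate_hz, max_lag_s = 5) {
  n <- min(length(a), length(b))
  a <- a[seq_len(n)] - mean(a[seq_len(n)])
  b <- b[seq_len(n)] - mean(b[seq_len(n)])
  if (sum(a^2) == 0 || sum(b^2) == 0)
    stop("cannot synchronise flat signals")
  L <- floor(max_lag_s * rate_hz)
  if (n - L < 10 * rate_hz)
    stop("overlap after maximum lag is below 10 s")
  lags <- -L:L
  cc <- vapply(lags, function(l) {
    # compare b[i] with a[i - l]
    ia <- max(1L, 1L - l):min(n, n - l)
    ib <- ia + l
    sa <- a[ia]; sb <- b[ib]
    den <- sqrt(sum(sa^2) * sum(sb^2))
    if (den == 0) -Inf else sum(sa * sb) / den
  }, numeric(1))
  best <- max(cc)
  cand <- lags[cc >= best - 1e-12]
  lag <- cand[which.min(abs(cand))]
  if (abs(lag) == L)
    warning("best lag is at the search boundary; low confidence")
  structure(lag / rate_hz, lag_samples = lag, correlation = best)
}

#' Median, IQR and outliers
#'
#' Quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7); outliers are values more than 1.5 times the
#' interquartile range below the 25th or above the 75th percentile.
#'
#' @param values Numeric vector (length >= 1).
#' @return List with `median`, `q1`, `q3`, `iqr`, `outliers` (values) and
#'   `outlier_idx` (positions).
#' @export
iqr_summary <- function(values) {
  stopifnot(length(values) >= 1L)
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[3] + 1.5 * iqr
  idx <- which(values < lo | values > hi)
  list(median = qs[2], q1 = qs[1], q3 = qs[3], iqr = iqr,
       outliers = values[idx], outlier_idx = idx)
}

#' Compare IK joint angles against a reference
#'
#' Aggregates the agreement and drift analyses for a fitted trajectory against
#' reference angles (e.g. synthetic ground truth or optically derived
#' kinematics): per-coordinate per-minute RMS differences, pooled median/IQR
#' with outliers (bilateral coordinates pooled by default), Pearson
#' correlations with the first-vs-last-minute change, and per-coordinate
#' drift fits.
#'
#' @param ik An `imu_ik` fit (or a `time` + coordinate-matrix list).
#' @param reference List with `time` and `coordinates` (matrix, degrees) on
#'   the same timestamps, or a data frame with a `time` column.
#' @param window_s RMS window (default 60 s).
#' @param pool_bilateral Pool `_r`/`_l` coordinate pairs (default TRUE).
#' @param coordinates Coordinates to compare (default: all shared rotational
#'   coordinates).
#' @return An object of class `kin_comparison`.
#' @export
compare_report <- function(ik, reference, window_s = 60,
                           pool_bilateral = TRUE, coordinates = NULL) {
  ik_co <- if (inherits(ik, "imu_ik")) ik$coordinates else ik$coordinates
  ik_t <- ik$time
  if (is.data.frame(reference)) {
    ref_t <- reference$time
    ref_co <- as.matrix(reference[, setdiff(names(reference), "time"),
                                  drop = FALSE])
  } else {
    ref_t <- reference$time
    ref_co <- reference$coordinates
  }
  if (length(ref_t) != length(ik_t) || max(abs(ref_t - ik_t)) > 1e-9)
    stop("reference is not synchronised with the fit (resample/shift first)")
  if (is.null(coordinates))
    coordinates <- setdiff(intersect(colnames(ik_co), colnames(ref_co)),
                           c("pelvis_tx", "pelvis_ty", "pelvis_tz"))
  nmin <- floor((ik_t[length(ik_t)] - ik_t[1]) / window_s)
  rms <- sapply(coordinates, function(cn)
    rms_per_window(ik_co[, cn], ref_co[, cn], ik_t, window_s))
  if (nmin == 1L) rms <- matrix(rms, nrow = 1, dimnames = list(NULL, coordinates))
  drift <- if (nmin >= 2) lapply(as.data.frame(rms), drift_fit) else NULL
  r_all <- vapply(coordinates, function(cn)
    pearson_r(ik_co[, cn], ref_co[, cn]), numeric(1))
  r_change <- if (nmin >= 2) vapply(coordinates, function(cn) {
    w1 <- ik_t < ik_t[1] + window_s
    wl <- ik_t >= ik_t[1] + (nmin - 1) * window_s &
      ik_t < ik_t[1] + nmin * window_s
    r1 <- tryCatch(pearson_r(ik_co[w1, cn], ref_co[w1, cn]),
                   error = function(e) NA_real_)
    rl <- tryCatch(pearson_r(ik_co[wl, cn], ref_co[wl, cn]),
                   error = function(e) NA_real_)
    rl - r1
  }, numeric(1)) else NULL
  pool <- if (pool_bilateral) sub("_(r|l)$", "", coordinates) else coordinates
  pooled <- lapply(split(coordinates, pool), function(cols)
    iqr_summary(as.numeric(rms[, cols])))
  structure(list(coordinates = coordinates, window_s = window_s,
                 per_minute_rms = rms, drift = drift, pearson = r_all,
                 pearson_change = r_change, pooled_rms = pooled,
                 n_windows = nmin),
            class = "kin_comparison")
}

#' @export
print.kin_comparison <- function(x, ...) {
  cat(sprintf("Kinematic comparison over %d windows of %g s\n",
              x$n_windows, x$window_s))
  med <- vapply(x$pooled_rms, `[[`, numeric(1), "median")
  iqr <- vapply(x$pooled_rms, `[[`, numeric(1), "iqr")
  tab <- data.frame(angle = names(x$pooled_rms),
                    median_rms_deg = round(med, 2),
                    iqr_deg = round(iqr, 2), row.names = NULL)
  print.data.frame(tab, row.names = FALSE)
  if (!is.null(x$drift)) {
    sl <- vapply(x$drift, `[[`, numeric(1), "slope")
    cat(sprintf("drift slopes: %.3f to %.3f deg/min\n", min(sl), max(sl)))
  }
  cat(sprintf("Pearson r: %.2f to %.2f\n", min(x$pearson), max(x$pearson)))
  invisible(x)
}
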