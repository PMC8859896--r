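# File formats.
#   * IMU CSV: columns time,gyro_x,gyro_y,gyro_z,acc_x,acc_y,acc_z,
#     mag_x,mag_y,mag_z (SI units, one file per sensor, header required;
#     columns are matched by name so ordering is free).
#   * STO dialect: a small tab-separated format with the header block
#       <name>\nnRows=<n>\nnColumns=<m>\nendheader
#     followed by a tab-separated column-name row and the data body.
#     Orientation files carry `time` then <sensor>_q_w,_q_x,_q_y,_q_z per
#     sensor; joint-angle files carry `time` then coordinate columns in
#     degrees.
# Round trips are lossless up to float formatting at 9 significant digits.

IMU_CSV_COLS <- c("time", "gyro_x", "gyro_y", "gyro_z",
                  "acc_x", "acc_y", "acc_z", "mag_x", "mag_y", "mag_z")

#' Read or write per-sensor IMU CSV files
#'
#' @param path File path.
#' @param sensor_id Sensor label; defaults to the file name sans extension.
#' @return `read_imu_csv` returns an [imu_series].
#' @export
read_imu_csv <- function(path, sensor_id = NULL) {
  df <- utils::read.csv(path, check.names = TRUE)
  missing_cols <- setdiff(IMU_CSV_COLS, names(df))
  if (length(missing_cols))
    stop("'", path, "': missing column(s) ", paste(missing_cols, collapse = ", "))
  if (any(!vapply(df[IMU_CSV_COLS], is.numeric, TRUE)))
    stop("'", path, "': non-numeric data in required columns")
  bad <- which(diff(df$time) <= 0)
  if (length(bad))
    stop("'", path, "': non-monotone time at data line ", bad[1] + 1)
  if (is.null(sensor_id))
    sensor_id <- sub("\\.[^.]*$", "", basename(path))
  imu_series(sensor_id, df$time,
             as.matrix(df[c("gyro_x", "gyro_y", "gyro_z")]),
             as.matrix(df[c("acc_x", "acc_y", "acc_z")]),
             as.matrix(df[c("mag_x", "mag_y", "mag_z")]))
}

#' @rdname read_imu_csv
#' @param series An [imu_series].
#' @export
write_imu_csv <- function(series, path) {
  stopifnot(inherits(series, "imu_series"))
  df <- data.frame(series$t, series$gyro, series$accel, series$mag)
  names(df) <- IMU_CSV_COLS
  utils::write.csv(format(df, digits = 9, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sto_write <- function(df, path, name) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               paste0("nRows=", nrow(df)),
               paste0("nColumns=", ncol(df)),
               "endheader",
               paste(names(df), collapse = "\t")), con)
  body <- apply(format(df, digits = 9, trim = TRUE, scientific = FALSE), 1,
                paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

sto_read <- function(path) {
  lines <- readLines(path)
  hend <- match("endheader", trimws(lines))
  if (is.na(hend)) stop("'", path, "': no 'endheader' line found")
  header <- lines[seq_len(hend - 1)]
  getfield <- function(key) {
    ln <- grep(paste0("^", key, "="), trimws(header), value = TRUE)
    if (!length(ln)) stop("'", path, "': header lacks '", key, "='")
    as.integer(sub(paste0("^", key, "="), "", ln[1]))
  }
  n_rows <- getfield("nRows")
  n_cols <- getfield("nColumns")
  cols <- strsplit(lines[hend + 1], "\t", fixed = TRUE)[[1]]
  if (length(cols) != n_cols)
    stop("'", path, "': header declares nColumns=", n_cols, " but the column",
         " row has ", length(cols), " names")
  body <- lines[-seq_len(hend + 1)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_rows)
    stop("'", path, "': header declares nRows=", n_rows, " but the body has ",
         length(body), " rows")
  parts <- strsplit(body, "\t", fixed = TRUE)
  ragged <- which(lengths(parts) != n_cols)
  if (length(ragged))
    stop("'", path, "': ragged row at data line ", ragged[1])
  df <- as.data.frame(matrix(as.numeric(unlist(parts)), n_rows, n_cols,
                             byrow = TRUE))
  names(df) <- cols
  if ("time" %in% cols) {
    bad <- which(diff(df$time) <= 0)
    if (length(bad))
      stop("'", path, "': non-monotone time at data line ", bad[1] + 1)
  }
  df
}

#' Read or write orientation time series in the STO dialect
#'
#' Columns are `time` then `<sensor>_q_w`, `_q_x`, `_q_y`, `_q_z` per sensor
#' (scalar-first quaternions, sensor-to-earth).
#'
#' @param path File path.
#' @return `read_orientations_sto` returns a named list of
#'   [orientation_series].
#' @export
read_orientations_sto <- function(path) {
  df <- sto_read(path)
  if (!"time" %in% names(df)) stop("'", path, "': no 'time' column")
  wcols <- grep("_q_w$", names(df), value = TRUE)
  if (!length(wcols)) stop("'", path, "': no quaternion columns found")
  out <- lapply(wcols, function(wc) {
    id <- sub("_q_w$", "", wc)
    need <- paste0(id, c("_q_w", "_q_x", "_q_y", "_q_z"))
    if (!all(need %in% names(df)))
      stop("'", path, "': incomplete quaternion columns for sensor '", id, "'")
    orientation_series(id, df$time, as.matrix(df[need]))
  })
  names(out) <- sub("_q_w$", "", wcols)
  out
}

#' @rdname read_orientations_sto
#' @param orientations Named list of [orientation_series] on shared
#'   timestamps.
#' @param name Header name line (provenance string allowed).
#' @export
write_orientations_sto <- function(orientations, path, name = "orientations") {
  if (inherits(orientations, "orientation_series"))
    orientations <- stats::setNames(list(orientations),
                                    orientations$sensor_id)
  t <- orientations[[1]]$t
  df <- data.frame(time = t)
  for (os in orientations) {
    if (length(os$t) != length(t) || max(abs(os$t - t)) > 1e-9)
      stop("orientation series do not share timestamps")
    qd <- as.data.frame(os$q)
    names(qd) <- paste0(os$sensor_id, c("_q_w", "_q_x", "_q_y", "_q_z"))
    df <- cbind(df, qd)
  }
  sto_write(df, path, name)
}

#' Read or write joint-angle tables (STO dialect or CSV)
#'
#' `time` in seconds plus one column per coordinate, angles in degrees.
#'
#' @param path File path; `write_angles` picks STO or CSV from the extension.
#' @return `read_angles` returns a data frame with a `time` column.
#' @export
read_angles <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"time" %in% names(df)) stop("'", path, "': no 'time' column")
    return(df)
  }
  sto_read(path)
}

#' @rdname read_angles
#' @param angles Data frame with `time` plus coordinate columns (degrees), or
#'   an `imu_ik` fit.
#' @param name STO header name line.
#' @export
write_angles <- function(angles, path, name = "joint_angles") {
  if (inherits(angles, "imu_ik")) angles <- as.data.frame(angles)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(format(angles, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  sto_write(angles, path, name)
}

#' Write IK residual diagnostics as CSV
#'
#' `time` plus one column of per-sensor IK orientation differences (degrees).
#'
#' @param ik An `imu_ik` fit.
#' @param path Output path.
#' @export
write_theta_csv <- function(ik, path) {
  df <- data.frame(time = ik$time, ik$theta, check.names = FALSE)
  utils::write.csv(format(df, digits = 9, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
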