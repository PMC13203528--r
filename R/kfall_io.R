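#' Read one KFall-style sensor CSV
#'
#' Reads a per-trial CSV with a header row and at least the six inertial
#' columns; only acceleration and gyroscope channels are consumed. Column
#' names are configurable to tolerate dialects. Acceleration units must be
#' stated explicitly (`"g"` or `"ms2"`): the free-fall gate of the
#' attitude filter is defined in g, so m/s^2 inputs are converted.
#'
#' @param file Path to the CSV file.
#' @param col_map Named list mapping `acc` and `gyr` to the three column
#'   names each (in x, y, z order).
#' @param accel_unit `"g"` or `"ms2"`.
#' @param fs Sampling rate (Hz).
#' @return A T x 6 matrix (ax, ay, az in g; wx, wy, wz in deg/s).
#' @export
read_kfall_trial <- function(file,
                             col_map = list(acc = c("AccX", "AccY", "AccZ"),
                                            gyr = c("GyrX", "GyrY", "GyrZ")),
                             accel_unit = c("g", "ms2"), fs = 100) {
  accel_unit <- match.arg(accel_unit)
  df <- utils::read.csv(file, check.names = FALSE)
  need <- c(col_map$acc, col_map$gyr)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns in ", basename(file), ": ",
         paste(miss, collapse = ", "))
  acc <- as.matrix(df[, col_map$acc])
  if (accel_unit == "ms2") acc <- acc / 9.80665
  gyr <- as.matrix(df[, col_map$gyr])
  out <- cbind(acc, gyr)
  colnames(out) <- c("ax", "ay", "az", "wx", "wy", "wz")
  out
}

#' Read a KFall-style label sheet
#'
#' @param file CSV with per-trial annotations; required columns (after
#'   mapping): task code, trial file, onset frame, impact frame.
#' @param col_map Named list mapping `task`, `file`, `onset`, `impact` to
#'   the sheet's column names.
#' @return Data frame with standardized columns `task`, `file`, `onset`,
#'   `impact`.
#' @export
read_kfall_labels <- function(file,
                              col_map = list(task = "Task Code (Task ID)",
                                             file = "Trial ID",
                                             onset = "Fall_onset_frame",
                                             impact = "Fall_impact_frame")) {
  df <- utils::read.csv(file, check.names = FALSE)
  miss <- setdiff(unlist(col_map), names(df))
  if (length(miss))
    stop("missing label columns: ", paste(miss, collapse = ", "))
  data.frame(task = df[[col_map$task]], file = df[[col_map$file]],
             onset = as.integer(df[[col_map$onset]]),
             impact = as.integer(df[[col_map$impact]]))
}

#' Write a trial as a KFall-style CSV
#'
#' Exports the 6 inertial channels with a frame counter, so synthetic and
#' real recordings share one reader path.
#'
#' @param trial An [imu_trial()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_trial_csv <- function(trial, file) {
  stopifnot(inherits(trial, "imu_trial"))
  df <- data.frame(FrameCounter = seq_len(nrow(trial$samples)),
                   AccX = trial$samples[, 1], AccY = trial$samples[, 2],
                   AccZ = trial$samples[, 3], GyrX = trial$samples[, 4],
                   GyrY = trial$samples[, 5], GyrZ = trial$samples[, 6])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
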