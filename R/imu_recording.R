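#' @keywords internal
"_PACKAGE"

# Standard gravity used for unit conversion and the sensor-range flag.
G_MS2 <- 9.80665

AXES <- c("ap", "ml", "v")

#' Construct a lumbar IMU recording
#'
#' Container for one test's raw tri-axial inertial stream as acquired at the
#' lower back (L5): per-sample nanosecond timestamps, acceleration in the
#' anatomical anteroposterior (AP), mediolateral (ML) and vertical (V) axes,
#' and optionally angular velocity about the same axes. Sampling need not be
#' uniform; downstream processing always goes through [resample_uniform()].
#'
#' Samples whose absolute acceleration exceeds the +/- 2 g range of a
#' smartphone accelerometer are flagged (never rejected) via the
#' `clipped` attribute; chair-stand processing winsorizes them.
#'
#' @param t_ns numeric vector of strictly increasing timestamps in nanoseconds.
#' @param acc numeric matrix or data frame with columns `ap`, `ml`, `v`,
#'   acceleration in m/s^2 (or g, see `acc_unit`).
#' @param gyro optional matrix/data frame with columns `ap`, `ml`, `v`,
#'   angular velocity in deg/s. May be `NULL` for tests that do not use it.
#' @param test_label one of `"QS"`, `"7MW"`, `"CST"`.
#' @param acc_unit `"ms2"` (default) or `"g"`; values in g are converted to
#'   m/s^2 (1 g = 9.80665 m/s^2) on construction.
#' @param meta list of free-form metadata (subject id, stopwatch duration in
#'   seconds, planted simulation ground truth, ...).
#' @return An object of class `imu_recording`.
#' @examples
#' t <- seq(0, 1, by = 0.01) * 1e9
#' acc <- cbind(ap = sin(seq_along(t)), ml = 0, v = 0)
#' rec <- imu_recording(t, acc, test_label = "QS")
#' @export
imu_recording <- function(t_ns, acc, gyro = NULL, test_label,
                          acc_unit = c("ms2", "g"), meta = list()) {
  acc_unit <- match.arg(acc_unit)
  test_label <- match.arg(test_label, c("QS", "7MW", "CST"))
  t_ns <- as.numeric(t_ns)
  if (length(t_ns) < 2L)
    stop("invalid recording: need at least 2 samples", call. = FALSE)
  if (any(diff(t_ns) <= 0))
    stop("invalid recording: timestamps must be strictly increasing",
         call. = FALSE)
  acc <- as_axis_matrix(acc, "acc")
  if (nrow(acc) != length(t_ns))
    stop("invalid recording: acc must have one sample per timestamp",
         call. = FALSE)
  if (acc_unit == "g") acc <- acc * G_MS2
  if (!is.null(gyro)) {
    gyro <- as_axis_matrix(gyro, "gyro")
    if (nrow(gyro) != length(t_ns))
      stop("invalid recording: gyro must have one sample per timestamp",
           call. = FALSE)
  }
  clipped <- which(rowSums(abs(acc) > 2 * G_MS2) > 0)
  structure(
    list(t_ns = t_ns, acc = acc, gyro = gyro, test_label = test_label,
         meta = meta),
    clipped = clipped,
    class = "imu_recording"
  )
}

as_axis_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) == 3L) colnames(x) <- AXES
  if (!all(AXES %in% colnames(x)))
    stop(sprintf("%s must have columns 'ap', 'ml', 'v'", what), call. = FALSE)
  storage.mode(x) <- "double"
  x[, AXES, drop = FALSE]
}

#' @export
print.imu_recording <- function(x, ...) {
  dur <- (x$t_ns[length(x$t_ns)] - x$t_ns[1]) / 1e9
  cat(sprintf("<imu_recording> %s: %d samples over %.2f s (%s gyroscope)\n",
              x$test_label, length(x$t_ns), dur,
              if (is.null(x$gyro)) "no" else "with"))
  nclip <- length(attr(x, "clipped"))
  if (nclip > 0) cat(sprintf("  %d sample(s) beyond +/-2 g flagged\n", nclip))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [imu_recording()].
#' @return numeric scalar, seconds between first and last sample.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  (rec$t_ns[length(rec$t_ns)] - rec$t_ns[1]) / 1e9
}

#' Read an IMU signal CSV
#'
#' Reads the package's interchange format: header
#' `t_ns,acc_ap,acc_ml,acc_v,gyro_ap,gyro_ml,gyro_v`, one row per sample;
#' the gyroscope columns may be absent.
#'
#' @param path path to the CSV file.
#' @param test_label test label to attach (`"QS"`, `"7MW"`, `"CST"`).
#' @param acc_unit unit of the acceleration columns, `"ms2"` or `"g"`.
#' @param meta metadata list passed on to [imu_recording()].
#' @return An `imu_recording`.
#' @export
read_imu_csv <- function(path, test_label, acc_unit = c("ms2", "g"),
                         meta = list()) {
  if (!file.exists(path)) stop("signal file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  need <- c("t_ns", "acc_ap", "acc_ml", "acc_v")
  if (!all(need %in% names(d)))
    stop("signal CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  acc <- cbind(ap = d$acc_ap, ml = d$acc_ml, v = d$acc_v)
  gyro <- NULL
  if (all(c("gyro_ap", "gyro_ml", "gyro_v") %in% names(d)))
    gyro <- cbind(ap = d$gyro_ap, ml = d$gyro_ml, v = d$gyro_v)
  imu_recording(d$t_ns, acc, gyro, test_label, acc_unit = acc_unit,
                meta = meta)
}

#' Write an IMU recording to the signal CSV format
#'
#' @param rec an [imu_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  d <- data.frame(t_ns = sprintf("%.0f", rec$t_ns),
                  acc_ap = rec$acc[, "ap"], acc_ml = rec$acc[, "ml"],
                  acc_v = rec$acc[, "v"])
  if (!is.null(rec$gyro)) {
    d$gyro_ap <- rec$gyro[, "ap"]
    d$gyro_ml <- rec$gyro[, "ml"]
    d$gyro_v <- rec$gyro[, "v"]
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
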