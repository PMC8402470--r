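#' FSR time series
#'
#' Container for the 16-channel grip-force stream acquired from the cane
#' handle, nominally sampled at 50 Hz, optionally carrying the cane
#' inclination angle measured by the cane's own IMU (used for stream
#' synchronization).
#'
#' @param time_s Strictly increasing timestamps in seconds.
#' @param forces Numeric matrix, one row per timestamp and 16 columns of
#'   non-negative sensor outputs (raw conditioned units; FSRs are reliable
#'   for timing, not absolute force).
#' @param cane_angle_deg Optional cane inclination from vertical, degrees,
#'   one value per timestamp.
#' @return An `fsr_series` object (list with `time_s`, `forces`,
#'   `cane_angle_deg`).
#' @export
fsr_series <- function(time_s, forces, cane_angle_deg = NULL) {
  time_s <- as.numeric(time_s)
  forces <- as.matrix(forces)
  if (nrow(forces) != length(time_s)) {
    stop("forces must have one row per timestamp", call. = FALSE)
  }
  if (ncol(forces) != 16L) {
    stop("forces must have 16 channels, got ", ncol(forces), call. = FALSE)
  }
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(forces < 0, na.rm = TRUE)) {
    stop("forces must be non-negative", call. = FALSE)
  }
  if (!is.null(cane_angle_deg) && length(cane_angle_deg) != length(time_s)) {
    stop("cane_angle_deg must match timestamps in length", call. = FALSE)
  }
  colnames(forces) <- sprintf("f%02d", 1:16)
  structure(
    list(
      time_s = time_s,
      forces = forces,
      cane_angle_deg = if (is.null(cane_angle_deg)) NULL else as.numeric(cane_angle_deg)
    ),
    class = "fsr_series"
  )
}

#' @export
print.fsr_series <- function(x, ...) {
  n <- length(x$time_s)
  rate <- if (n > 1L) 1 / stats::median(diff(x$time_s)) else NA_real_
  cat(sprintf(
    "FSR series: %d samples, %.1f s, ~%.1f Hz, cane angle: %s\n",
    n, diff(range(x$time_s)), rate,
    if (is.null(x$cane_angle_deg)) "absent" else "present"
  ))
  invisible(x)
}

#' Reference kinematics time series
#'
#' Container for the reference motion-capture stream used to segment the
#' gait: per-foot speed and sagittal foot orientation for the tracked
#' (impaired-side) foot and the opposite foot, the tracked-shank angle from
#' horizontal, the distance between the feet, and the cane inclination from
#' vertical as seen by the reference system. Sampled at a higher rate than
#' the cane stream (typically 100 Hz or more).
#'
#' @param data Data frame with columns `time_s`, `foot_speed_tracked`,
#'   `foot_speed_opposite` (m/s), `foot_angle_tracked`,
#'   `foot_angle_opposite` (degrees, 0 = foot flat), `tibia_angle` (degrees
#'   from horizontal, 90 = vertical shank), `feet_distance` (metres, >= 0)
#'   and `cane_angle_deg` (degrees from vertical).
#' @return A `kinematics_series` data frame.
#' @export
kinematics_series <- function(data) {
  required <- c(
    "time_s", "foot_speed_tracked", "foot_speed_opposite",
    "foot_angle_tracked", "foot_angle_opposite", "tibia_angle",
    "feet_distance", "cane_angle_deg"
  )
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop(
      "kinematics data missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(data) > 1L && any(diff(data$time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(data$feet_distance < 0, na.rm = TRUE)) {
    stop("feet_distance must be non-negative", call. = FALSE)
  }
  data <- as.data.frame(data)[, required]
  class(data) <- c("kinematics_series", "data.frame")
  data
}

#' @export
print.kinematics_series <- function(x, ...) {
  n <- nrow(x)
  rate <- if (n > 1L) 1 / stats::median(diff(x$time_s)) else NA_real_
  cat(sprintf(
    "Kinematics series: %d samples, %.1f s, ~%.1f Hz\n",
    n, diff(range(x$time_s)), rate
  ))
  invisible(x)
}
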