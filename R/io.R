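# Delimited-text readers and writers for every stream the pipeline
# consumes or emits. All files are tab-separated with a header row;
# timestamps are seconds from recording start.

read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE),
    error = function(e) {
      stop("malformed ", what, " file '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(
      what, " file '", path, "' missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Read and write a handle layout file
#'
#' Tab-separated with columns `sensor_id`, `x_mm`, `z_mm`, `side`; must
#' describe exactly 16 sensors (10 top, 6 bottom).
#'
#' @param path File path.
#' @return `read_handle_layout()` returns a [handle_layout()].
#' @export
read_handle_layout <- function(path) {
  df <- read_delim_checked(path, c("sensor_id", "x_mm", "z_mm", "side"), "layout")
  handle_layout(df$sensor_id, df$x_mm, df$z_mm, df$side)
}

#' @rdname read_handle_layout
#' @param layout A [handle_layout()].
#' @export
write_handle_layout <- function(layout, path) {
  validate_handle_layout(layout)
  utils::write.table(
    data.frame(
      sensor_id = layout$sensor_id, x_mm = layout$x, z_mm = layout$z,
      side = layout$side
    ),
    path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write an FSR series file
#'
#' Tab-separated with columns `time_s`, `f01`..`f16` and optionally
#' `cane_angle_deg`.
#'
#' @param path File path.
#' @return `read_fsr_series()` returns an [fsr_series()].
#' @export
read_fsr_series <- function(path) {
  fcols <- sprintf("f%02d", 1:16)
  df <- read_delim_checked(path, c("time_s", fcols), "FSR series")
  fsr_series(
    df$time_s, as.matrix(df[, fcols]),
    cane_angle_deg = df[["cane_angle_deg"]]
  )
}

#' @rdname read_fsr_series
#' @param series An [fsr_series()].
#' @export
write_fsr_series <- function(series, path) {
  df <- data.frame(time_s = series$time_s, series$forces)
  if (!is.null(series$cane_angle_deg)) df$cane_angle_deg <- series$cane_angle_deg
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a kinematics series file
#'
#' Tab-separated with the named columns of [kinematics_series()].
#'
#' @param path File path.
#' @return `read_kinematics_series()` returns a [kinematics_series()].
#' @export
read_kinematics_series <- function(path) {
  df <- read_delim_checked(path, c(
    "time_s", "foot_speed_tracked", "foot_speed_opposite",
    "foot_angle_tracked", "foot_angle_opposite", "tibia_angle",
    "feet_distance", "cane_angle_deg"
  ), "kinematics")
  kinematics_series(df)
}

#' @rdname read_kinematics_series
#' @param kin A [kinematics_series()].
#' @export
write_kinematics_series <- function(kin, path) {
  utils::write.table(as.data.frame(kin), path,
    sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  invisible(path)
}

#' Write the event table
#'
#' Tab-separated table of consolidated events: variable, kind, phase,
#' number of strides detected, median offset and interquartile range in
#' seconds.
#'
#' @param events An `event_summary` from [consolidate_events()].
#' @param path File path.
#' @export
write_event_table <- function(events, path) {
  df <- as.data.frame(events)[, c(
    "variable", "kind", "phase", "n_strides_detected", "median_offset",
    "iqr_offset"
  )]
  names(df)[5:6] <- c("median_offset_s", "iqr_s")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
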