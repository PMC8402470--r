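#' Handle sensor layout
#'
#' Constructs a validated handle layout: the sagittal-plane coordinates of the
#' 16 FSR units on the cane handle and their partition into the 10 top-side
#' sensors (ids 1-10, under the palm) and the 6 bottom-side sensors
#' (ids 11-16, under the fingers). Coordinates are in millimetres in a local
#' frame whose z-axis is aligned with the cane shaft.
#'
#' @param sensor_id Integer ids 1..16.
#' @param x,z Sensor coordinates in millimetres.
#' @param side "top" or "bottom" per sensor.
#' @return A `handle_layout` data frame with columns `sensor_id`, `x`, `z`,
#'   `side`.
#' @seealso [default_handle_layout()] for the bundled measured layout.
#' @export
handle_layout <- function(sensor_id, x, z, side) {
  layout <- data.frame(
    sensor_id = as.integer(sensor_id),
    x = as.numeric(x),
    z = as.numeric(z),
    side = as.character(side),
    stringsAsFactors = FALSE
  )
  validate_handle_layout(layout)
  class(layout) <- c("handle_layout", "data.frame")
  layout
}

validate_handle_layout <- function(layout) {
  required <- c("sensor_id", "x", "z", "side")
  if (!all(required %in% names(layout))) {
    stop("layout must have columns ", paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(layout) != 16L) {
    stop("layout must describe exactly 16 sensors, got ", nrow(layout),
      call. = FALSE
    )
  }
  if (anyDuplicated(layout$sensor_id)) {
    stop("sensor ids must be unique", call. = FALSE)
  }
  if (!setequal(layout$sensor_id, 1:16)) {
    stop("sensor ids must be 1..16", call. = FALSE)
  }
  if (!all(layout$side %in% c("top", "bottom"))) {
    stop("side must be 'top' or 'bottom'", call. = FALSE)
  }
  if (sum(layout$side == "top") != 10L || sum(layout$side == "bottom") != 6L) {
    stop("layout must have 10 top-side and 6 bottom-side sensors",
      call. = FALSE
    )
  }
  if (!all(is.finite(layout$x)) || !all(is.finite(layout$z))) {
    stop("sensor coordinates must be finite", call. = FALSE)
  }
  invisible(layout)
}

#' Default handle layout
#'
#' The measured locations of the 16 FSR units on the instrumented cane
#' handle, in millimetres in the handle's local sagittal frame. Sensors 1-10
#' lie on the top side of the handle and 11-16 on the bottom side.
#'
#' @return A [handle_layout()] data frame with 16 rows.
#' @export
#' @examples
#' lay <- default_handle_layout()
#' subset(lay, sensor_id == 1)
default_handle_layout <- function() {
  handle_layout(
    sensor_id = 1:16,
    x = c(
      -15.21, -5.29, 4.71, 14.58, 24.44, 34.50, 44.60, 54.71, 64.80, 74.86,
      -19.66, 19.12, 30.40, 42.10, 53.15, 64.65
    ),
    z = c(
      85.05, 84.95, 85.22, 85.61, 86.72, 87.72, 88.19, 88.10, 87.47, 86.27,
      49.89, 53.30, 54.54, 54.85, 54.74, 54.08
    ),
    side = rep(c("top", "bottom"), times = c(10L, 6L))
  )
}

#' @export
print.handle_layout <- function(x, ...) {
  cat(
    "Cane handle FSR layout:", nrow(x), "sensors (",
    sum(x$side == "top"), "top /", sum(x$side == "bottom"), "bottom )\n"
  )
  print.data.frame(x, ...)
  invisible(x)
}
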