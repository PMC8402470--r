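#' Grip-pressure derived variables
#'
#' Computes, per sample, the six variables derived from the 16 handle FSR
#' outputs:
#' \describe{
#'   \item{CoMXUp}{force-weighted mean x of the 10 top-side sensors
#'     (grip centre of pressure along the handle axis, palm side),}
#'   \item{CoMXDown}{force-weighted mean x of the 6 bottom-side sensors,}
#'   \item{CoMX, CoMZ}{force-weighted mean x and z over all 16 sensors,}
#'   \item{MPUp, MPDown}{mean pressure (mean sensor output) over the top and
#'     bottom side respectively.}
#' }
#' A centre-of-pressure value is undefined when the summed force of its
#' sensor group is zero (e.g. full unloading during the cane swing); such
#' samples are reported as `NA` rather than fabricated, and the mean
#' pressures are then 0.
#'
#' @param series An [fsr_series()].
#' @param layout A [handle_layout()]; defaults to the bundled handle.
#' @return A `derived_series`: list with `time_s` and a data frame `data`
#'   holding columns `CoMXUp`, `CoMXDown`, `CoMX`, `CoMZ` (millimetres,
#'   `NA` = undefined) and `MPUp`, `MPDown` (force units).
#' @export
#' @examples
#' lay <- default_handle_layout()
#' f <- matrix(0, 2, 16)
#' f[, 3] <- 1 # only sensor 3 loaded
#' d <- compute_derived(fsr_series(c(0, 0.02), f), lay)
#' d$data$CoMXUp # equals sensor 3's x coordinate
compute_derived <- function(series, layout = default_handle_layout()) {
  if (!inherits(series, "fsr_series")) {
    stop("series must be an fsr_series", call. = FALSE)
  }
  validate_handle_layout(layout)
  forces <- series$forces
  if (ncol(forces) != nrow(layout)) {
    stop("channel count does not match layout", call. = FALSE)
  }
  ord <- order(layout$sensor_id)
  x <- layout$x[ord]
  z <- layout$z[ord]
  top <- layout$side[ord] == "top"
  n_up <- sum(top)
  n_down <- sum(!top)

  wmean <- function(f, coord) {
    denom <- rowSums(f)
    out <- as.numeric(f %*% coord) / denom
    out[denom == 0] <- NA_real_
    out
  }
  f_top <- forces[, top, drop = FALSE]
  f_bot <- forces[, !top, drop = FALSE]

  data <- data.frame(
    CoMXUp = wmean(f_top, x[top]),
    CoMXDown = wmean(f_bot, x[!top]),
    CoMX = wmean(forces, x),
    CoMZ = wmean(forces, z),
    MPUp = rowSums(f_top) / n_up,
    MPDown = rowSums(f_bot) / n_down
  )
  structure(
    list(time_s = series$time_s, data = data),
    class = "derived_series"
  )
}

#' Time derivatives of the derived variables
#'
#' Appends, for every base channel present, a `d`-prefixed channel holding
#' its derivative with respect to time (e.g. `dCoMZ` for `CoMZ`), estimated
#' by central finite differences on the interior samples and one-sided
#' differences at the ends. In the event pipeline this is applied after
#' Savitzky-Golay smoothing to limit noise amplification.
#'
#' @param series A `derived_series` with at least 3 samples.
#' @return The series with derivative channels added (units per second).
#'   Samples adjacent to an undefined (`NA`) parent sample are undefined.
#' @export
differentiate <- function(series) {
  stopifnot(inherits(series, "derived_series"))
  if (length(series$time_s) < 3L) {
    stop("at least 3 samples are required to differentiate", call. = FALSE)
  }
  t <- series$time_s
  for (ch in intersect(BASE_CHANNELS, names(series$data))) {
    series$data[[paste0("d", ch)]] <- pracma::gradient(series$data[[ch]], t)
  }
  series
}

#' @export
print.derived_series <- function(x, ...) {
  cat(sprintf(
    "Derived grip series: %d samples, channels: %s\n",
    length(x$time_s), paste(names(x$data), collapse = ", ")
  ))
  invisible(x)
}
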