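#' Normalize a signal to the unit range
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 1; the
#' first step of the stream-synchronization procedure, making the two cane
#' inclination signals comparable regardless of sensor gain and offset.
#'
#' @param x Numeric vector with at least 2 samples and non-zero range.
#' @return Rescaled vector in \[0, 1\].
#' @export
normalize_unit_range <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    stop("degenerate signal: zero range", call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

# Local maxima of x with prominence >= prom. Prominence of a peak is its
# height above the higher of the two lowest points separating it from
# higher terrain (or the signal edge) on each side. Plateaus of equal
# samples count once, at their middle sample.
local_maxima <- function(x, prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- seq_along(r$values)
  pk <- k[k > 1L & k < length(k)]
  pk <- pk[which(r$values[pk] > r$values[pk - 1L] & r$values[pk] > r$values[pk + 1L])]
  peaks <- (starts[pk] + ends[pk]) %/% 2L
  if (!length(peaks) || prom <= 0) return(peaks)
  keep <- vapply(peaks, function(p) {
    left <- x[1:p]
    higher_l <- which(left > x[p])
    base_l <- min(left[if (length(higher_l)) (max(higher_l)):p else 1:p])
    right <- x[p:n]
    higher_r <- which(right > x[p])
    base_r <- min(right[if (length(higher_r)) 1:(min(higher_r)) else seq_along(right)])
    (x[p] - max(base_l, base_r)) >= prom
  }, logical(1))
  peaks[keep]
}

#' Trim a signal to its first and last local peak
#'
#' The second synchronization step: the portions of the signal before the
#' first and after the last local maximum are removed, so both streams span
#' the same cyclic content before correlation. A peak must rise at least
#' `prominence_frac` of the signal range above its surroundings, so noise
#' ripples do not define the trim bounds.
#'
#' @param x Numeric vector containing at least two qualifying local maxima.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   signal range.
#' @return List with `signal` (the trimmed segment, bounds inclusive),
#'   `start` and `end` (indices into `x`).
#' @export
trim_to_peaks <- function(x, prominence_frac = 0.05) {
  x <- as.numeric(x)
  prom <- prominence_frac * diff(range(x, na.rm = TRUE))
  peaks <- local_maxima(x, prom)
  if (length(peaks) < 2L) {
    stop("insufficient structure: fewer than 2 local peaks", call. = FALSE)
  }
  a <- peaks[1L]
  b <- peaks[length(peaks)]
  list(signal = x[a:b], start = a, end = b)
}

#' Synchronize the cane stream with the reference stream
#'
#' Estimates the clock offset between the cane's acquisition stream and the
#' reference kinematics stream from their two cane-inclination signals,
#' which measure the same physical angle. The procedure: (1) normalize both
#' signals to \[0, 1\]; (2) trim each to its first and last local peak;
#' (3) upsample the lower-rate cane signal by linear interpolation onto the
#' reference sampling period; (4) shift one signal against the other in
#' integer reference samples and evaluate the Pearson correlation at each
#' shift; (5) report the lag maximizing the correlation. Adding the lag to
#' every cane-stream timestamp aligns the streams.
#'
#' @param cane_angle List or data frame with `time_s` and `angle_deg`
#'   (the cane's own inclination signal, ~50 Hz).
#' @param ref_angle Same structure for the reference stream (higher rate).
#' @param max_lag_s Half-width of the shift search window in seconds.
#' @param prominence_frac Peak prominence floor passed to
#'   [trim_to_peaks()].
#' @return A `sync_result` list: `lag` (seconds to add to cane-stream
#'   timestamps), `peak_correlation`, `resampled_length` (cane samples
#'   after upsampling).
#' @export
synchronize <- function(cane_angle, ref_angle, max_lag_s = 5,
                        prominence_frac = 0.05) {
  get_tv <- function(s, nm) {
    if (is.null(s$time_s) || is.null(s$angle_deg)) {
      stop(nm, " must have fields time_s and angle_deg", call. = FALSE)
    }
    list(t = as.numeric(s$time_s), v = as.numeric(s$angle_deg))
  }
  cane <- get_tv(cane_angle, "cane_angle")
  ref <- get_tv(ref_angle, "ref_angle")

  cane$v <- normalize_unit_range(cane$v)
  ref$v <- normalize_unit_range(ref$v)
  ctr <- trim_to_peaks(cane$v, prominence_frac)
  rtr <- trim_to_peaks(ref$v, prominence_frac)
  ct <- cane$t[ctr$start:ctr$end]
  cv <- ctr$signal
  rt <- ref$t[rtr$start:rtr$end]
  rv <- rtr$signal

  dt <- stats::median(diff(rt))
  # upsample the cane segment onto the reference sampling period
  cg <- seq(ct[1L], ct[length(ct)], by = dt)
  cvu <- stats::approx(ct, cv, xout = cg)$y

  base <- rt[1L] - cg[1L] # lag implied by aligning the two first peaks
  kmax <- floor(max_lag_s / dt) # search window is centered on that alignment
  ks <- -kmax:kmax
  nr <- length(rv)
  nc <- length(cvu)
  min_overlap <- max(ceiling(0.5 * min(nr, nc)), 10L)

  best <- NULL
  for (k in ks) {
    # ref index i matches cane index i - k
    i1 <- max(1L, 1L + k)
    i2 <- min(nr, nc + k)
    if (i2 - i1 + 1L < min_overlap) next
    a <- rv[i1:i2]
    b <- cvu[(i1 - k):(i2 - k)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    lag <- base + k * dt
    if (is.null(best) || r > best$r + 1e-12 ||
      (abs(r - best$r) <= 1e-12 && abs(lag) < abs(best$lag))) {
      best <- list(r = r, lag = lag, k = k)
    }
  }
  if (is.null(best)) {
    stop("synchronization failed: no admissible shift with defined correlation",
      call. = FALSE
    )
  }
  structure(
    list(
      lag = best$lag,
      peak_correlation = min(best$r, 1),
      resampled_length = nc
    ),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "Stream sync: lag = %+.4f s (add to cane timestamps), peak r = %.4f\n",
    x$lag, x$peak_correlation
  ))
  invisible(x)
}
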