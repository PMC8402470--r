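#' Savitzky-Golay smoothing of the derived variables
#'
#' Removes high-frequency noise peaks from every channel of a derived
#' series with a 3rd-order Savitzky-Golay filter. Undefined (`NA`) samples
#' are bridged by linear interpolation for the fit and restored to `NA`
#' afterwards, so they never contribute fabricated values downstream.
#'
#' @param series A `derived_series`.
#' @param window Filter window length in samples; must be odd and larger
#'   than the polynomial order 3. The default, 11 samples (0.22 s at
#'   50 Hz), is shorter than any gait phase at ordinary cadence, so peak
#'   timing is preserved.
#' @return The smoothed series.
#' @export
smooth_derived <- function(series, window = 11L) {
  stopifnot(inherits(series, "derived_series"))
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= 3L) {
    stop("window must be odd and greater than the polynomial order 3",
      call. = FALSE
    )
  }
  n <- length(series$time_s)
  if (n < window) {
    stop("series shorter than the smoothing window", call. = FALSE)
  }
  for (ch in names(series$data)) {
    y <- series$data[[ch]]
    bad <- !is.finite(y)
    if (all(bad)) next
    if (any(bad)) {
      y <- stats::approx(seq_len(n)[!bad], y[!bad], xout = seq_len(n),
        rule = 2
      )$y
    }
    y <- signal::sgolayfilt(y, p = 3, n = window)
    y[bad] <- NA_real_
    series$data[[ch]] <- y
  }
  series
}

#' Select the central strides of a recording
#'
#' Keeps the `n` consecutive strides centred in the recording, discarding
#' the less regular strides near the start and end of the test; with an odd
#' surplus the extra stride is discarded from the start.
#'
#' @param tl A `phase_timeline` with at least `n` strides.
#' @param n Number of strides to keep (default 30).
#' @return The trimmed `phase_timeline`.
#' @export
select_central_strides <- function(tl, n = 30L) {
  stopifnot(inherits(tl, "phase_timeline"))
  n <- as.integer(n)
  surplus <- nrow(tl) - n
  if (surplus < 0L) {
    stop("insufficient data: ", nrow(tl), " strides, need ", n, call. = FALSE)
  }
  front <- ceiling(surplus / 2)
  out <- tl[(front + 1L):(front + n), , drop = FALSE]
  out$stride <- seq_len(n)
  rownames(out) <- NULL
  attr(out, "t_end") <- attr(tl, "t_end")
  class(out) <- class(tl)
  out
}

#' Detect per-stride extrema of the grip variables
#'
#' Finds, stride by stride and channel by channel, the local maxima and
#' minima of the derived grip-pressure variables and refers each one to the
#' nearest gait-phase onset. The reported offset is the event time minus
#' the onset time, so 0 marks the phase start and negative offsets mean the
#' event anticipates the phase.
#'
#' An extremum must rise (or fall) at least `prominence_frac` of the
#' channel's interquartile range over the analyzed strides above its
#' surroundings. Candidate reference onsets are all onsets of the stride
#' plus the next stride's initial contact; terminal stance is excluded by
#' default because it sits too close to pre-swing to separate events
#' between them. Near-equidistant ties go to the following onset (the
#' anticipating reading).
#'
#' @param series A smoothed (and optionally differentiated)
#'   `derived_series`, on the same clock as the timeline.
#' @param tl A `phase_timeline` (typically the central strides).
#' @param prominence_frac Prominence floor as a fraction of the channel
#'   IQR.
#' @param exclude_phases Phase labels never used as event references.
#' @return Data frame of event candidates: `variable`, `kind`
#'   (`"max"`/`"min"`), `stride_id`, `time`, `referenced_phase`, `offset`
#'   (seconds).
#' @export
detect_stride_extrema <- function(series, tl, prominence_frac = 0.05,
                                  exclude_phases = "terminal_stance") {
  stopifnot(inherits(series, "derived_series"), inherits(tl, "phase_timeline"))
  t <- series$time_s
  phases <- setdiff(gait_phases(), exclude_phases)
  out <- list()
  for (ch in names(series$data)) {
    y_all <- series$data[[ch]]
    span <- t >= tl$initial_contact_loading_response[1L] & t <= tl$end[nrow(tl)]
    iqr <- stats::IQR(y_all[span], na.rm = TRUE)
    if (!is.finite(iqr)) next
    # the absolute term keeps numerically flat channels from reporting
    # floating-point ripples as extrema
    prom <- max(
      prominence_frac * iqr,
      1e-9 * max(abs(y_all[span]), 1, na.rm = TRUE)
    )
    for (s in seq_len(nrow(tl))) {
      idx <- which(t >= tl$initial_contact_loading_response[s] & t < tl$end[s])
      if (length(idx) < 3L) next
      y <- y_all[idx]
      for (kind in c("max", "min")) {
        yy <- if (kind == "max") y else -y
        yy[!is.finite(yy)] <- -Inf
        pk <- local_maxima(yy, prom)
        for (p in pk) {
          tev <- t[idx[p]]
          # candidate onsets: this stride's phases + next initial contact
          cand_t <- c(
            as.numeric(tl[s, phases]),
            tl$end[s]
          )
          cand_lab <- c(phases, "initial_contact_loading_response")
          off <- tev - cand_t
          best <- which(abs(abs(off) - min(abs(off))) <= 1e-9)
          if (length(best) > 1L) best <- best[off[best] <= 0][1L] # anticipating
          if (is.na(best)) best <- which.min(abs(off))
          out[[length(out) + 1L]] <- data.frame(
            variable = ch, kind = kind, stride_id = tl$stride[s],
            time = tev, referenced_phase = cand_lab[best],
            offset = off[best], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      variable = character(), kind = character(), stride_id = integer(),
      time = numeric(), referenced_phase = character(), offset = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' Consolidate candidates into stride-consistent events
#'
#' Groups extremum candidates by (variable, kind, referenced phase) and
#' keeps only groups present in at least `min_strides` of the
#' `total_strides` analyzed strides — by default 25 of 30, so only events
#' that recur reliably across the gait cycles are reported. When a stride
#' contributes several candidates to a group, the one closest to the phase
#' onset represents it.
#'
#' @param cands Candidate data frame from [detect_stride_extrema()].
#' @param min_strides Minimum number of strides an event must appear in.
#' @param total_strides Number of strides analyzed.
#' @return An `event_summary` data frame: `variable`, `kind`, `phase`,
#'   `n_strides_detected`, `median_offset`, `iqr_offset` (seconds), plus a
#'   list column `offsets` with the per-stride offsets.
#' @export
consolidate_events <- function(cands, min_strides = 25L, total_strides = 30L) {
  min_strides <- as.integer(min_strides)
  total_strides <- as.integer(total_strides)
  empty <- data.frame(
    variable = character(), kind = character(), phase = character(),
    n_strides_detected = integer(), median_offset = numeric(),
    iqr_offset = numeric(), stringsAsFactors = FALSE
  )
  empty$offsets <- list()
  if (!nrow(cands)) {
    class(empty) <- c("event_summary", "data.frame")
    return(empty)
  }
  key <- interaction(cands$variable, cands$kind, cands$referenced_phase,
    drop = TRUE
  )
  rows <- lapply(split(cands, key), function(g) {
    per_stride <- lapply(split(g, g$stride_id), function(gs) {
      gs[which.min(abs(gs$offset)), , drop = FALSE]
    })
    g1 <- do.call(rbind, per_stride)
    n <- nrow(g1)
    if (n < min_strides) return(NULL)
    out <- data.frame(
      variable = g1$variable[1L], kind = g1$kind[1L],
      phase = g1$referenced_phase[1L], n_strides_detected = n,
      median_offset = stats::median(g1$offset),
      iqr_offset = stats::IQR(g1$offset), stringsAsFactors = FALSE
    )
    out$offsets <- list(g1$offset)
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    class(empty) <- c("event_summary", "data.frame")
    return(empty)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$variable, res$phase, res$kind), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "min_strides") <- min_strides
  attr(res, "total_strides") <- total_strides
  class(res) <- c("event_summary", "data.frame")
  res
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf(
    "Consolidated gait events: %d (threshold %s/%s strides)\n", nrow(x),
    attr(x, "min_strides") %||% "?", attr(x, "total_strides") %||% "?"
  ))
  if (nrow(x)) {
    show <- x[, c(
      "variable", "kind", "phase", "n_strides_detected",
      "median_offset", "iqr_offset"
    )]
    print.data.frame(show, digits = 4, ...)
  }
  invisible(x)
}

#' Stride-time normalization of the derived variables
#'
#' Resamples every stride of every channel onto a common grid on \[0, 1\],
#' where 0 is the stride's initial contact and 1 the next initial contact,
#' and computes the mean curve across strides together with the mean
#' cycle fraction at which each phase starts — the representation used to
#' inspect how the variables evolve over the gait cycle.
#'
#' @param series A `derived_series`.
#' @param tl A `phase_timeline` with at least one stride.
#' @param n_points Number of grid points on \[0, 1\].
#' @return List with `u` (the grid), `curves` (per channel, a strides x
#'   points matrix), `mean` (points x channels matrix) and
#'   `phase_fractions` (strides x phases matrix of onset fractions) plus
#'   `mean_phase_fractions`.
#' @export
normalize_stride_time <- function(series, tl, n_points = 101L) {
  stopifnot(inherits(series, "derived_series"), inherits(tl, "phase_timeline"))
  if (nrow(tl) < 1L) stop("timeline must contain at least one stride", call. = FALSE)
  u <- seq(0, 1, length.out = n_points)
  t <- series$time_s
  chans <- names(series$data)
  curves <- lapply(chans, function(ch) {
    m <- matrix(NA_real_, nrow(tl), n_points)
    for (s in seq_len(nrow(tl))) {
      a <- tl$initial_contact_loading_response[s]
      b <- tl$end[s]
      idx <- which(t >= a & t <= b)
      if (length(idx) < 2L) next
      y <- series$data[[ch]][idx]
      ok <- is.finite(y)
      if (sum(ok) < 2L) next
      m[s, ] <- stats::approx((t[idx][ok] - a) / (b - a), y[ok],
        xout = u, rule = 2
      )$y
    }
    m
  })
  names(curves) <- chans
  mean_mat <- vapply(curves, function(m) colMeans(m, na.rm = TRUE),
    numeric(n_points)
  )
  pf <- as.matrix(tl[, gait_phases()])
  pf <- (pf - tl$initial_contact_loading_response) /
    (tl$end - tl$initial_contact_loading_response)
  list(
    u = u, curves = curves, mean = mean_mat,
    phase_fractions = pf,
    mean_phase_fractions = colMeans(pf)
  )
}
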