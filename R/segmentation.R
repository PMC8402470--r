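#' Gait segmentation configuration
#'
#' Thresholds of the rule-based segmentation of the reference kinematics
#' into gait phases. Defaults are the values used with the inertial
#' reference system: a foot is considered in stance when its speed is below
#' 0.4 m/s and in swing above 0.8 m/s; toe-off requires the foot pitched
#' toe-down beyond -9 degrees; the feet-adjacent event requires a local
#' minimum of the inter-feet distance below 0.4 m; the terminal-swing event
#' is the shank reaching 90 degrees from horizontal (vertical tibia).
#'
#' @param stance_speed_threshold Foot speed (m/s) below which the foot is in
#'   stance. Must be smaller than `swing_speed_threshold`.
#' @param swing_speed_threshold Foot speed (m/s) above which the foot is in
#'   swing.
#' @param foot_angle_threshold Sagittal foot angle (degrees) below which the
#'   foot counts as toe-down at toe-off.
#' @param feet_distance_threshold Inter-feet distance (m) a feet-adjacent
#'   minimum must stay under.
#' @param tibia_vertical_angle Shank angle from horizontal (degrees) whose
#'   crossing marks terminal swing.
#' @param hysteresis_samples Number of consecutive samples a threshold
#'   condition must hold before a crossing is accepted (chatter guard).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(stance_speed_threshold = 0.4,
                                swing_speed_threshold = 0.8,
                                foot_angle_threshold = -9,
                                feet_distance_threshold = 0.4,
                                tibia_vertical_angle = 90,
                                hysteresis_samples = 2L) {
  vals <- c(
    stance_speed_threshold, swing_speed_threshold, foot_angle_threshold,
    feet_distance_threshold, tibia_vertical_angle
  )
  if (!all(is.finite(vals))) stop("thresholds must be finite", call. = FALSE)
  if (stance_speed_threshold >= swing_speed_threshold) {
    stop("stance_speed_threshold must be below swing_speed_threshold",
      call. = FALSE
    )
  }
  structure(
    list(
      stance_speed_threshold = stance_speed_threshold,
      swing_speed_threshold = swing_speed_threshold,
      foot_angle_threshold = foot_angle_threshold,
      feet_distance_threshold = feet_distance_threshold,
      tibia_vertical_angle = tibia_vertical_angle,
      hysteresis_samples = as.integer(hysteresis_samples)
    ),
    class = "segmentation_config"
  )
}

# First index i > after where x falls below thr (x[i-1] >= thr, x[i] < thr)
# and stays below for `hold` samples. Returns NA_integer_ if none in
# (after, upto].
first_falling <- function(x, thr, after, upto = length(x), hold = 2L) {
  lo <- max(after + 1L, 2L)
  if (lo > upto) return(NA_integer_)
  idx <- lo:upto
  cand <- idx[x[idx] < thr & x[idx - 1L] >= thr]
  for (i in cand) {
    j <- i:min(i + hold - 1L, length(x))
    if (all(x[j] < thr)) return(i)
  }
  NA_integer_
}

first_rising <- function(x, thr, after, upto = length(x), hold = 2L) {
  lo <- max(after + 1L, 2L)
  if (lo > upto) return(NA_integer_)
  idx <- lo:upto
  cand <- idx[x[idx] > thr & x[idx - 1L] <= thr]
  for (i in cand) {
    j <- i:min(i + hold - 1L, length(x))
    if (all(x[j] > thr)) return(i)
  }
  NA_integer_
}

#' Segment reference kinematics into gait phases
#'
#' Rule-based segmentation of a stride into seven labeled phases (the
#' initial-contact phase is merged with loading response). Events, in stride
#' order, are detected as:
#' \enumerate{
#'   \item initial contact / loading response: tracked-foot speed falls
#'     below `stance_speed_threshold` after a swing interval;
#'   \item mid stance: opposite-foot speed rises above
#'     `swing_speed_threshold` (opposite toe-off);
#'   \item terminal stance: tracked heel rise, i.e. the foot angle rises
#'     above 0 degrees while the foot speed is still in stance;
#'   \item pre-swing: opposite-foot initial contact (opposite speed falls
#'     below `stance_speed_threshold`);
#'   \item initial swing: tracked-foot speed exceeds
#'     `swing_speed_threshold` with the foot pitched below
#'     `foot_angle_threshold` (toe-off);
#'   \item mid swing: feet adjacent — a local minimum of the inter-feet
#'     distance below `feet_distance_threshold`;
#'   \item terminal swing: the shank crosses `tibia_vertical_angle`
#'     (onset time linearly interpolated between samples).
#' }
#' Threshold crossings must hold for `hysteresis_samples` consecutive
#' samples. Only complete strides — all seven onsets found, in order,
#' closed by the next initial contact — are returned; incomplete leading and
#' trailing strides are dropped.
#'
#' @param kin A [kinematics_series()] spanning at least 3 complete strides.
#' @param cfg A [segmentation_config()].
#' @return A `phase_timeline` data frame: one row per stride with columns
#'   `stride`, the seven phase-onset times (seconds) and `end` (the next
#'   initial contact). Attribute `n_dropped` counts rejected strides.
#' @export
segment_gait <- function(kin, cfg = segmentation_config()) {
  if (!inherits(kin, "kinematics_series")) kin <- kinematics_series(kin)
  stopifnot(inherits(cfg, "segmentation_config"))
  t <- kin$time_s
  if (any(diff(t) <= 0)) stop("non-monotone timestamps", call. = FALSE)
  h <- cfg$hysteresis_samples
  v_tr <- kin$foot_speed_tracked
  v_op <- kin$foot_speed_opposite
  ang <- kin$foot_angle_tracked
  tib <- kin$tibia_angle
  dst <- kin$feet_distance
  n <- length(t)

  # Initial contacts: falling stance-threshold crossings of the tracked
  # foot preceded by a swing interval (speed above swing threshold).
  ics <- integer(0)
  pos <- 1L
  repeat {
    i <- first_falling(v_tr, cfg$stance_speed_threshold, pos, n, h)
    if (is.na(i)) break
    prev <- if (length(ics)) ics[length(ics)] else 1L
    if (any(v_tr[prev:i] > cfg$swing_speed_threshold)) ics <- c(ics, i)
    pos <- i
  }
  if (length(ics) < 2L) {
    stop("insufficient data: fewer than 3 complete strides detected",
      call. = FALSE
    )
  }

  strides <- vector("list", length(ics) - 1L)
  dropped <- 0L
  for (k in seq_len(length(ics) - 1L)) {
    a <- ics[k]
    b <- ics[k + 1L]
    ms <- first_rising(v_op, cfg$swing_speed_threshold, a, b - 1L, h)
    ts <- if (is.na(ms)) NA_integer_ else {
      i <- first_rising(ang, 0, ms, b - 1L, h)
      if (!is.na(i) && v_tr[i] >= cfg$stance_speed_threshold) i <- NA_integer_
      i
    }
    ps <- if (is.na(ts)) NA_integer_ else {
      first_falling(v_op, cfg$stance_speed_threshold, ts, b - 1L, h)
    }
    is_ <- if (is.na(ps)) NA_integer_ else {
      i <- first_rising(v_tr, cfg$swing_speed_threshold, ps, b - 1L, h)
      if (!is.na(i) && ang[i] >= cfg$foot_angle_threshold) i <- NA_integer_
      i
    }
    mw <- if (is.na(is_)) NA_integer_ else {
      idx <- (is_ + 1L):(b - 1L)
      if (length(idx) < 3L) NA_integer_ else {
        seg <- dst[idx]
        mins <- local_maxima(-seg)
        mins <- mins[seg[mins] < cfg$feet_distance_threshold]
        if (!length(mins)) NA_integer_ else idx[mins[which.min(seg[mins])]]
      }
    }
    tw_t <- if (is.na(mw)) NA_real_ else {
      s <- sign(tib[mw:(b - 1L)] - cfg$tibia_vertical_angle)
      flip <- which(s[-1L] != s[-length(s)] & s[-1L] != 0)[1L]
      if (is.na(flip)) NA_real_ else {
        i <- mw + flip - 1L # last index before the crossing
        frac <- (cfg$tibia_vertical_angle - tib[i]) / (tib[i + 1L] - tib[i])
        t[i] + frac * (t[i + 1L] - t[i])
      }
    }
    onsets <- c(
      t[a],
      if (is.na(ms)) NA_real_ else t[ms],
      if (is.na(ts)) NA_real_ else t[ts],
      if (is.na(ps)) NA_real_ else t[ps],
      if (is.na(is_)) NA_real_ else t[is_],
      if (is.na(mw)) NA_real_ else t[mw],
      tw_t
    )
    if (anyNA(onsets) || any(diff(onsets) <= 0) || onsets[7L] >= t[b]) {
      dropped <- dropped + 1L
      next
    }
    strides[[k]] <- c(onsets, t[b])
  }
  strides <- strides[!vapply(strides, is.null, logical(1))]
  if (length(strides) < 3L) {
    stop("insufficient data: fewer than 3 complete strides segmented",
      call. = FALSE
    )
  }
  tl <- as.data.frame(do.call(rbind, strides))
  names(tl) <- c(gait_phases(), "end")
  tl <- cbind(stride = seq_len(nrow(tl)), tl)
  attr(tl, "n_dropped") <- dropped
  attr(tl, "t_end") <- t[n]
  class(tl) <- c("phase_timeline", "data.frame")
  tl
}

#' Build a phase timeline from onset times
#'
#' Low-level constructor used by the segmenter and the simulator's ground
#' truth. `onsets` holds one row per stride with the seven phase-onset
#' times; `end` is each stride's closing initial contact.
#'
#' @param onsets Data frame or matrix with one column per phase label of
#'   [gait_phases()], in seconds.
#' @param end Closing initial-contact time per stride (seconds).
#' @param t_end Optional recording end time (used for the last stride's
#'   duration when `end` is absent).
#' @return A `phase_timeline` data frame.
#' @export
phase_timeline <- function(onsets, end = NULL, t_end = NULL) {
  onsets <- as.data.frame(onsets)
  if (!all(gait_phases() %in% names(onsets))) {
    stop("onsets must contain every phase label", call. = FALSE)
  }
  tl <- onsets[, gait_phases(), drop = FALSE]
  if (!is.null(end)) tl$end <- end
  ok <- apply(tl[, gait_phases(), drop = FALSE], 1L, function(r) {
    !anyNA(r) && all(diff(r) > 0)
  })
  if (!all(ok)) stop("phase onsets must be strictly increasing", call. = FALSE)
  tl <- cbind(stride = seq_len(nrow(tl)), tl)
  attr(tl, "t_end") <- t_end
  class(tl) <- c("phase_timeline", "data.frame")
  tl
}

#' Stride durations
#'
#' Duration of each stride: the time from its initial contact to the next
#' stride's initial contact; the last stride is closed by its own `end`
#' column when present, otherwise by the recording end.
#'
#' @param tl A `phase_timeline`.
#' @return Numeric vector of durations in seconds.
#' @export
stride_durations <- function(tl) {
  if (!inherits(tl, "phase_timeline") || nrow(tl) < 1L) {
    stop("timeline must contain at least one stride", call. = FALSE)
  }
  ic <- tl$initial_contact_loading_response
  last_end <- if (!is.null(tl$end)) {
    tl$end[nrow(tl)]
  } else if (!is.null(attr(tl, "t_end"))) {
    attr(tl, "t_end")
  } else {
    stop("cannot close the last stride: no 'end' column or recording end",
      call. = FALSE
    )
  }
  c(diff(ic), last_end - ic[length(ic)])
}

#' @export
print.phase_timeline <- function(x, ...) {
  cat(sprintf(
    "Phase timeline: %d strides, median stride %.3f s (%d rejected)\n",
    nrow(x), stats::median(stride_durations(x)),
    attr(x, "n_dropped") %||% 0L
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
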