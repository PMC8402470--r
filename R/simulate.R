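# Periodic piecewise-linear template: knots (u, y) on the unit gait cycle,
# evaluated at arbitrary cycle phase with wrap-around continuity.
pw_periodic <- function(u, ku, ky) {
  ku <- ku %% 1
  o <- order(ku)
  ku <- ku[o]
  ky <- ky[o]
  n <- length(ku)
  stats::approx(
    c(ku[n] - 1, ku, ku[1] + 1), c(ky[n], ky, ky[1]),
    xout = u %% 1
  )$y
}

#' Describe a grip event to plant in the simulation
#'
#' @param channel One of the 12 variable names (`CoMXUp`, ..., `MPDown`, or
#'   a `d`-prefixed derivative).
#' @param kind `"max"` or `"min"`.
#' @param fraction Gait-cycle fraction in (0, 1) at which the extremum of
#'   the (derived) variable occurs.
#' @param amplitude Bump amplitude in force units added to the sensor
#'   pattern.
#' @param jitter_sd Per-stride Gaussian jitter of the event time, seconds.
#' @param strides Optional integer vector of stride indices (1-based) that
#'   carry the event; `NULL` = every stride.
#' @return A `planted_event` list.
#' @export
planted_event <- function(channel, kind = c("max", "min"), fraction,
                          amplitude = 2, jitter_sd = 0.01, strides = NULL) {
  kind <- match.arg(kind)
  if (!channel %in% c(BASE_CHANNELS, DERIV_CHANNELS)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      channel = channel, kind = kind, fraction = fraction,
      amplitude = amplitude, jitter_sd = jitter_sd, strides = strides
    ),
    class = "planted_event"
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic gait and grip generator. Defaults emulate
#' the study conditions the pipeline is designed for: treadmill walking
#' with a contralateral cane moved in synchrony with the impaired leg, the
#' handle stream scanned at 50 Hz and the reference kinematics at a higher
#' rate. Phase onsets follow the standard gait cycle (stance about 60\% of
#' the stride, the merged initial-contact/loading-response phase about the
#' first 10\%).
#'
#' @param n_strides Number of complete strides to generate (>= 3).
#' @param stride_period Stride duration in seconds.
#' @param phase_fractions Named vector of cycle fractions of the phase
#'   onsets after initial contact (which is 0), strictly increasing in
#'   stride order, all in (0, 1).
#' @param fsr_rate,ref_rate Sampling rates (Hz) of the cane stream and the
#'   reference stream; the reference must be faster.
#' @param injected_lag Clock offset in seconds between the two streams: a
#'   cane sample stamped t was acquired at reference time t + injected_lag.
#' @param planted_events List of [planted_event()]s; the default plants the
#'   canonical pair seen in grip recordings: a CoMZ maximum shortly before
#'   pre-swing and a CoMZ minimum in terminal swing, anticipating the next
#'   initial contact.
#' @param noise Per-stream additive Gaussian noise standard deviations:
#'   list with `fsr` (force units), `speed` (m/s), `angle` (degrees),
#'   `distance` (m), `cane` (degrees). A single number (e.g. 0) applies to
#'   all streams.
#' @param feet_min_distance Inter-feet distance (m) at the feet-adjacent
#'   instant.
#' @param base_force Baseline per-sensor grip force (arbitrary units).
#' @param event_width Gaussian bump width (cycle fractions, sd).
#' @param cane_amplitude Cane inclination oscillation amplitude, degrees.
#' @param amplitude_cv Per-stride coefficient of variation of the cane
#'   swing amplitude (makes strides distinguishable for synchronization).
#' @param seed Integer seed; the generator draws everything from a single
#'   seeded stream, so equal seeds give identical recordings.
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(n_strides = 40L,
                            stride_period = 1.1,
                            phase_fractions = c(
                              mid_stance = 0.10,
                              terminal_stance = 0.30,
                              pre_swing = 0.50,
                              initial_swing = 0.60,
                              mid_swing = 0.73,
                              terminal_swing = 0.87
                            ),
                            fsr_rate = 50,
                            ref_rate = 100,
                            injected_lag = 0,
                            planted_events = list(
                              planted_event("CoMZ", "max", fraction = 0.45),
                              planted_event("CoMZ", "min", fraction = 0.95)
                            ),
                            noise = list(
                              fsr = 0.2, speed = 0.02, angle = 0.5,
                              distance = 0.005, cane = 0.2
                            ),
                            feet_min_distance = 0.12,
                            base_force = 10,
                            event_width = 0.05,
                            cane_amplitude = 15,
                            amplitude_cv = 0.08,
                            seed = 1L) {
  need <- c(
    "mid_stance", "terminal_stance", "pre_swing", "initial_swing",
    "mid_swing", "terminal_swing"
  )
  if (!all(need %in% names(phase_fractions))) {
    stop("phase_fractions must name: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  pf <- phase_fractions[need]
  if (any(pf <= 0) || any(pf >= 1) || any(diff(pf) <= 0)) {
    stop("phase fractions must be strictly increasing within (0, 1)",
      call. = FALSE
    )
  }
  if (pf["mid_swing"] <= 0.5) {
    stop("mid_swing fraction must exceed 0.5 (swing-side feet-adjacent)",
      call. = FALSE
    )
  }
  if (n_strides < 3L) stop("n_strides must be at least 3", call. = FALSE)
  if (fsr_rate <= 0 || ref_rate <= 0) stop("rates must be positive", call. = FALSE)
  if (is.numeric(noise) && length(noise) == 1L) {
    noise <- list(
      fsr = noise, speed = noise, angle = noise, distance = noise,
      cane = noise
    )
  }
  if (inherits(planted_events, "planted_event")) {
    planted_events <- list(planted_events)
  }
  structure(
    list(
      n_strides = as.integer(n_strides), stride_period = stride_period,
      phase_fractions = pf, fsr_rate = fsr_rate, ref_rate = ref_rate,
      injected_lag = injected_lag, planted_events = planted_events,
      noise = noise, feet_min_distance = feet_min_distance,
      base_force = base_force, event_width = event_width,
      cane_amplitude = cane_amplitude, amplitude_cv = amplitude_cv,
      seed = as.integer(seed)
    ),
    class = "gait_sim_config"
  )
}

# Direction of force change across the 16 sensors that moves a derived
# variable upward; scaled to unit maximum absolute entry. Directions for
# ratio variables sum to zero within each sensor group, so planting a bump
# leaves the group's total force (the denominator) unchanged.
event_direction <- function(channel, layout) {
  ord <- order(layout$sensor_id)
  x <- layout$x[ord]
  z <- layout$z[ord]
  top <- layout$side[ord] == "top"
  d <- numeric(16L)
  centred <- function(v, grp) {
    w <- numeric(16L)
    w[grp] <- v[grp] - mean(v[grp])
    w / max(abs(w))
  }
  switch(channel,
    CoMXUp = centred(x, top),
    CoMXDown = centred(x, !top),
    CoMX = centred(x, rep(TRUE, 16L)),
    CoMZ = centred(z, rep(TRUE, 16L)),
    MPUp = {
      d[top] <- 1
      d
    },
    MPDown = {
      d[!top] <- 1
      d
    },
    stop("no direction for channel ", channel, call. = FALSE)
  )
}

#' Simulate a synthetic gait and grip recording
#'
#' Generates a ground-truthed pair of acquisition streams: a reference
#' kinematics stream whose foot-speed, foot-angle, shank-angle and
#' feet-distance curves realize the configured phase onsets exactly under
#' the segmentation rules, and a cane-handle stream whose 16 FSR channels
#' follow a stride-periodic grip pattern (loading during cane stance,
#' unloading during cane swing) with Gaussian force bumps planting extrema
#' of chosen derived variables at chosen cycle fractions. The cane
#' inclination appears in both streams; the cane-stream copy is shifted by
#' the injected lag and sampled at the cane rate. Per-stride amplitude
#' variation of the cane swing and additive noise make the recording
#' realistically imperfect while every quantity of interest stays known.
#'
#' @param cfg A [gait_sim_config()].
#' @return List with `fsr` (an [fsr_series()] carrying `cane_angle_deg`),
#'   `kin` (a [kinematics_series()]), and `truth`: list with `timeline`
#'   (the true `phase_timeline`), `lag` (the injected lag), `events`
#'   (data frame of per-stride planted extremum times, reference clock) and
#'   `cane_peak_times` (true cane-swing peak instants).
#' @export
simulate_gait <- function(cfg = gait_sim_config()) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  set.seed(cfg$seed)
  T_ <- cfg$stride_period
  pf <- cfg$phase_fractions
  ms <- pf[["mid_stance"]]
  ts <- pf[["terminal_stance"]]
  ps <- pf[["pre_swing"]]
  is_ <- pf[["initial_swing"]]
  mw <- pf[["mid_swing"]]
  tw <- pf[["terminal_swing"]]
  t0 <- 0.5 * T_ # first initial contact
  t_total <- (cfg$n_strides + 1.2) * T_
  t_ref <- seq(0, t_total, by = 1 / cfg$ref_rate)
  t_cane <- seq(0, t_total, by = 1 / cfg$fsr_rate)
  phase_of <- function(t) (t - t0) / T_

  # --- stochastic elements, all drawn up front from the single stream ---
  n_amp <- cfg$n_strides + 20L
  amp_fac <- 1 + cfg$amplitude_cv * stats::rnorm(n_amp) # cane swing amplitude
  jitters <- lapply(cfg$planted_events, function(ev) {
    ev$jitter_sd * stats::rnorm(cfg$n_strides)
  })

  # --- kinematics templates (piecewise linear on the unit cycle) ---
  speed_knots <- function(up, down) {
    # crosses the swing threshold (0.8) upward exactly at `up` and the
    # stance threshold (0.4) downward exactly at `down`
    dw <- down %% 1
    peak <- (up + dw + (dw <= up)) / 2
    list(
      u = c(down + 0.04, up - 0.04, up, peak, down),
      y = c(0.05, 0.05, 0.8, 2.5, 0.4)
    )
  }
  sk_tr <- speed_knots(is_, 1)
  sk_op <- speed_knots(ms, ps)
  ang_knots <- list(
    u = c(0, 0.05, ts - 0.03, ts, ps, is_, is_ + 0.03, tw),
    y = c(0, -3, -3, 0, 15, -15, -20, 0)
  )
  tib_knots <- list(
    u = c(0, 0.08, is_, mw, tw),
    y = c(100, 75, 45, 60, 90)
  )
  dmin <- cfg$feet_min_distance
  dst_knots <- list(
    u = c(mw - 0.5, mw - 0.25, mw, mw + 0.25),
    y = c(dmin, 0.75, dmin, 0.75)
  )

  u_ref <- phase_of(t_ref)
  nz <- cfg$noise
  nref <- length(t_ref)
  cane_angle_fun <- function(t) {
    u <- phase_of(t)
    k <- pmin(pmax(floor(u) + 10L, 1L), n_amp)
    cfg$cane_amplitude * amp_fac[k] * sin(2 * pi * u)
  }
  kin <- kinematics_series(data.frame(
    time_s = t_ref,
    foot_speed_tracked = pmax(
      0, pw_periodic(u_ref, sk_tr$u, sk_tr$y) + nz$speed * stats::rnorm(nref)
    ),
    foot_speed_opposite = pmax(
      0, pw_periodic(u_ref, sk_op$u, sk_op$y) + nz$speed * stats::rnorm(nref)
    ),
    foot_angle_tracked = pw_periodic(u_ref, ang_knots$u, ang_knots$y) +
      nz$angle * stats::rnorm(nref),
    foot_angle_opposite = pw_periodic(u_ref - 0.5, ang_knots$u, ang_knots$y) +
      nz$angle * stats::rnorm(nref),
    tibia_angle = pw_periodic(u_ref, tib_knots$u, tib_knots$y) +
      nz$angle * stats::rnorm(nref),
    feet_distance = pmax(
      0, pw_periodic(u_ref, dst_knots$u, dst_knots$y) +
        nz$distance * stats::rnorm(nref)
    ),
    cane_angle_deg = cane_angle_fun(t_ref) + nz$cane * stats::rnorm(nref)
  ))

  # --- grip pattern: loading during cane stance, planted event bumps ---
  layout <- default_handle_layout()
  env_knots <- list(
    u = c(0, 0.05, 0.55, 0.65, 0.95),
    y = c(0.9, 1.0, 1.0, 0.35, 0.35)
  )
  t_gait <- t_cane + cfg$injected_lag # cane samples in reference time
  u_cane <- phase_of(t_gait)
  env_vals <- pw_periodic(u_cane, env_knots$u, env_knots$y)
  forces <- matrix(
    cfg$base_force * env_vals,
    nrow = length(t_cane), ncol = 16L
  )
  truth_events <- list()
  w <- cfg$event_width
  for (e in seq_along(cfg$planted_events)) {
    ev <- cfg$planted_events[[e]]
    deriv <- ev$channel %in% DERIV_CHANNELS
    parent <- if (deriv) sub("^d", "", ev$channel) else ev$channel
    dir_ <- event_direction(parent, layout)
    if (!deriv && ev$kind == "min") dir_ <- -dir_
    # for derivative channels a positive parent bump centred w after (max)
    # or before (min) the target puts the derivative extremum on target
    centre_frac <- ev$fraction + if (!deriv) 0 else if (ev$kind == "max") w else -w
    strides <- if (is.null(ev$strides)) seq_len(cfg$n_strides) else ev$strides
    for (k in strides) {
      t_c <- t0 + (k - 1 + centre_frac) * T_ + jitters[[e]][k]
      # scaling by the loading envelope keeps the centre-of-pressure
      # perturbation proportional to the bump itself (the envelope cancels
      # in the ratio), so the planted extremum lands exactly on target
      bump <- ev$amplitude * env_vals *
        exp(-((t_gait - t_c)^2) / (2 * (w * T_)^2))
      forces <- forces + outer(bump, dir_)
      truth_events[[length(truth_events) + 1L]] <- data.frame(
        event_id = e, channel = ev$channel, kind = ev$kind, stride = k,
        time = t0 + (k - 1 + ev$fraction) * T_ + jitters[[e]][k]
      )
    }
  }
  forces <- forces + nz$fsr * stats::rnorm(length(forces))
  forces <- pmax(forces, 0)
  fsr <- fsr_series(
    time_s = t_cane, forces = forces,
    cane_angle_deg = cane_angle_fun(t_cane + cfg$injected_lag) +
      nz$cane * stats::rnorm(length(t_cane))
  )

  # --- ground truth ---
  k <- seq_len(cfg$n_strides) - 1L
  onsets <- data.frame(
    initial_contact_loading_response = t0 + k * T_,
    mid_stance = t0 + (k + ms) * T_,
    terminal_stance = t0 + (k + ts) * T_,
    pre_swing = t0 + (k + ps) * T_,
    initial_swing = t0 + (k + is_) * T_,
    mid_swing = t0 + (k + mw) * T_,
    terminal_swing = t0 + (k + tw) * T_
  )
  truth <- list(
    timeline = phase_timeline(onsets, end = t0 + (k + 1) * T_, t_end = t_total),
    lag = cfg$injected_lag,
    events = if (length(truth_events)) {
      do.call(rbind, truth_events)
    } else {
      data.frame(
        event_id = integer(), channel = character(), kind = character(),
        stride = integer(), time = numeric()
      )
    },
    cane_peak_times = t0 + (seq(-1, cfg$n_strides + 1) + 0.25) * T_
  )
  list(fsr = fsr, kin = kin, truth = truth)
}

#' Corrupt a stream with dropouts and spikes
#'
#' Robustness harness: zeroes short spans of samples and injects additive
#' spikes into a stream, leaving any ground truth untouched. Useful to
#' check that the smoothing stage absorbs transient sensor faults.
#'
#' @param series An [fsr_series()], [kinematics_series()] or numeric
#'   vector.
#' @param dropout_fraction Fraction of samples zeroed, in \[0, 1); applied
#'   as spans of `span` consecutive samples.
#' @param spike_rate Per-sample probability of an additive spike.
#' @param spike_magnitude Spike size; default 10 standard deviations of the
#'   signal.
#' @param span Dropout span length in samples.
#' @return The corrupted stream, same class as the input.
#' @export
corrupt <- function(series, dropout_fraction = 0, spike_rate = 0,
                    spike_magnitude = NULL, span = 5L) {
  if (dropout_fraction < 0 || dropout_fraction >= 1 ||
    spike_rate < 0 || spike_rate >= 1) {
    stop("fractions must be in [0, 1)", call. = FALSE)
  }
  corrupt_vec <- function(y, floor0 = FALSE) {
    n <- length(y)
    mag <- spike_magnitude %||% (10 * stats::sd(y))
    n_spans <- round(dropout_fraction * n / span)
    if (n_spans > 0) {
      starts <- sample.int(max(n - span + 1L, 1L), n_spans)
      for (s in starts) y[s:min(s + span - 1L, n)] <- 0
    }
    if (spike_rate > 0) {
      hit <- stats::runif(n) < spike_rate
      y[hit] <- y[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) * mag
    }
    if (floor0) y <- pmax(y, 0)
    y
  }
  if (inherits(series, "fsr_series")) {
    series$forces <- apply(series$forces, 2L, corrupt_vec, floor0 = TRUE)
    colnames(series$forces) <- sprintf("f%02d", 1:16)
    series
  } else if (inherits(series, "kinematics_series")) {
    for (ch in setdiff(names(series), "time_s")) {
      series[[ch]] <- corrupt_vec(series[[ch]])
    }
    series
  } else if (is.numeric(series)) {
    corrupt_vec(series)
  } else {
    stop("unsupported stream type", call. = FALSE)
  }
}
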