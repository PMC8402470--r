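# Independent naive oracle for the six grip variables: explicit per-sample,
# per-sensor loops, no shared code with compute_derived().
naive_derived <- function(forces, layout) {
  n <- nrow(forces)
  out <- data.frame(
    CoMXUp = rep(NA_real_, n), CoMXDown = NA_real_, CoMX = NA_real_,
    CoMZ = NA_real_, MPUp = NA_real_, MPDown = NA_real_
  )
  for (s in seq_len(n)) {
    num_xu <- num_xd <- num_x <- num_z <- 0
    den_u <- den_d <- 0
    for (i in 1:16) {
      row <- layout[layout$sensor_id == i, ]
      f <- forces[s, i]
      num_x <- num_x + f * row$x
      num_z <- num_z + f * row$z
      if (row$side == "top") {
        num_xu <- num_xu + f * row$x
        den_u <- den_u + f
      } else {
        num_xd <- num_xd + f * row$x
        den_d <- den_d + f
      }
    }
    den <- den_u + den_d
    out$CoMXUp[s] <- if (den_u > 0) num_xu / den_u else NA_real_
    out$CoMXDown[s] <- if (den_d > 0) num_xd / den_d else NA_real_
    out$CoMX[s] <- if (den > 0) num_x / den else NA_real_
    out$CoMZ[s] <- if (den > 0) num_z / den else NA_real_
    out$MPUp[s] <- den_u / 10
    out$MPDown[s] <- den_d / 6
  }
  out
}

# A kinematics frame describing quiet standing (no strides).
standing_kinematics <- function(duration = 10, rate = 100) {
  t <- seq(0, duration, by = 1 / rate)
  kinematics_series(data.frame(
    time_s = t, foot_speed_tracked = 0.01, foot_speed_opposite = 0.01,
    foot_angle_tracked = 0, foot_angle_opposite = 0, tibia_angle = 70,
    feet_distance = 0.2, cane_angle_deg = 0
  ))
}

# Build a derived_series directly from per-channel functions of time.
synthetic_derived <- function(t, channels) {
  structure(
    list(time_s = t, data = as.data.frame(channels)),
    class = "derived_series"
  )
}

# A regular timeline with given stride period and phase fractions.
regular_timeline <- function(n_strides, period = 1.1, t0 = 0,
                             fractions = c(
                               mid_stance = 0.10, terminal_stance = 0.30,
                               pre_swing = 0.50, initial_swing = 0.60,
                               mid_swing = 0.73, terminal_swing = 0.87
                             )) {
  k <- seq_len(n_strides) - 1
  onsets <- data.frame(
    initial_contact_loading_response = t0 + k * period,
    mid_stance = t0 + (k + fractions[["mid_stance"]]) * period,
    terminal_stance = t0 + (k + fractions[["terminal_stance"]]) * period,
    pre_swing = t0 + (k + fractions[["pre_swing"]]) * period,
    initial_swing = t0 + (k + fractions[["initial_swing"]]) * period,
    mid_swing = t0 + (k + fractions[["mid_swing"]]) * period,
    terminal_swing = t0 + (k + fractions[["terminal_swing"]]) * period
  )
  phase_timeline(onsets, end = t0 + (k + 1) * period,
    t_end = t0 + n_strides * period
  )
}

# Match segmented strides to ground-truth strides by initial contact and
# return the worst absolute onset error (seconds) per phase.
onset_errors <- function(tl, truth_tl) {
  j <- vapply(
    tl$initial_contact_loading_response,
    function(a) which.min(abs(truth_tl$initial_contact_loading_response - a)),
    integer(1)
  )
  vapply(gait_phases(), function(p) {
    max(abs(tl[[p]] - truth_tl[[p]][j]))
  }, numeric(1))
}
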