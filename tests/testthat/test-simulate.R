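test_that("simulated recordings have the configured size and ground truth", {
  sim <- simulate_gait(gait_sim_config(n_strides = 40, stride_period = 1.1, seed = 1))
  expect_equal(nrow(sim$truth$timeline), 40L)
  dur <- max(sim$kin$time_s)
  expect_gt(dur, 44) # 40 strides of 1.1 s plus lead-in/lead-out margin
  expect_lt(dur, 47)
  expect_equal(1 / stats::median(diff(sim$fsr$time_s)), 50, tolerance = 1e-6)
  expect_equal(1 / stats::median(diff(sim$kin$time_s)), 100, tolerance = 1e-6)
  expect_true(all(sim$fsr$forces >= 0))
  # the true timeline is internally consistent
  for (s in seq_len(nrow(sim$truth$timeline))) {
    expect_true(all(diff(as.numeric(sim$truth$timeline[s, gait_phases()])) > 0))
  }
})

test_that("equal seeds reproduce the recording bitwise; seeds matter", {
  cfg <- gait_sim_config(n_strides = 5, seed = 12)
  a <- simulate_gait(cfg)
  b <- simulate_gait(cfg)
  expect_identical(a$fsr$forces, b$fsr$forces)
  expect_identical(a$kin, b$kin)
  expect_identical(a$truth$events, b$truth$events)
  c_ <- simulate_gait(gait_sim_config(n_strides = 5, seed = 13))
  expect_false(identical(a$fsr$forces, c_$fsr$forces))
})

test_that("infeasible configurations are rejected", {
  expect_error(
    gait_sim_config(phase_fractions = c(
      mid_stance = 0.3, terminal_stance = 0.2, pre_swing = 0.5,
      initial_swing = 0.6, mid_swing = 0.73, terminal_swing = 0.87
    )),
    "strictly increasing"
  )
  expect_error(gait_sim_config(n_strides = 2), "at least 3")
  expect_error(planted_event("NotAChannel", "max", 0.5), "unknown channel")
  expect_error(planted_event("CoMZ", "max", 1.2), "in \\(0, 1\\)")
})

test_that("a noiseless, jitter-free recording yields exact event recovery", {
  evs <- list(
    planted_event("CoMZ", "max", 0.45, jitter_sd = 0),
    planted_event("CoMXUp", "min", 0.20, jitter_sd = 0)
  )
  rep_ <- run_pipeline(pipeline_config(
    simulate = gait_sim_config(noise = 0, planted_events = evs),
    seed = 21
  ))
  ev <- as.data.frame(rep_$events)
  cz <- ev[ev$variable == "CoMZ" & ev$kind == "max" & ev$phase == "pre_swing", ]
  expect_equal(nrow(cz), 1L)
  # planted 5% of a 1.1 s cycle before pre-swing: offset -0.055 s,
  # recovered within one 50 Hz sample
  expect_lt(abs(cz$median_offset - (-0.055)), 0.021)
  cx <- ev[ev$variable == "CoMXUp" & ev$kind == "min" & ev$phase == "mid_stance", ]
  expect_equal(nrow(cx), 1L)
  expect_lt(abs(cx$median_offset - (0.20 - 0.10) * 1.1), 0.021)
})

test_that("derivative-channel events are planted where requested", {
  evs <- list(planted_event("dCoMZ", "max", 0.40, jitter_sd = 0, amplitude = 3))
  rep_ <- run_pipeline(pipeline_config(
    simulate = gait_sim_config(noise = 0, planted_events = evs),
    seed = 22
  ))
  ev <- as.data.frame(rep_$events)
  # 40% of the cycle: 0.11 s before pre-swing (terminal stance, though
  # closer, is not an event reference by default)
  dz <- ev[ev$variable == "dCoMZ" & ev$kind == "max" & ev$phase == "pre_swing", ]
  expect_equal(nrow(dz), 1L)
  expect_equal(dz$n_strides_detected, 30L)
  expect_lt(abs(dz$median_offset - (-0.11)), 0.021)
})

test_that("corruption zeroes the expected share and spares ground truth", {
  sim <- simulate_gait(gait_sim_config(n_strides = 6, seed = 3))
  same <- corrupt(sim$fsr, dropout_fraction = 0, spike_rate = 0)
  expect_identical(same$forces, sim$fsr$forces)
  fr <- vapply(1:6, function(s) {
    set.seed(s)
    cor_ <- corrupt(sim$fsr, dropout_fraction = 0.05)
    mean(cor_$forces[, 1] == 0)
  }, numeric(1))
  expect_equal(mean(fr), 0.05, tolerance = 0.015)
  expect_error(corrupt(sim$fsr, dropout_fraction = 1.2), "\\[0, 1\\)")
})

test_that("smoothing absorbs injected spikes without losing events", {
  cfg <- gait_sim_config(
    noise = 0,
    planted_events = list(planted_event("CoMZ", "max", 0.45, jitter_sd = 0)),
    seed = 30
  )
  sim <- simulate_gait(cfg)
  set.seed(99)
  spiky <- corrupt(sim$fsr, spike_rate = 0.002, spike_magnitude = 5)
  d <- differentiate(smooth_derived(compute_derived(spiky), 11))
  tl <- select_central_strides(segment_gait(sim$kin), 30)
  ev <- consolidate_events(detect_stride_extrema(d, tl), 25, 30)
  ev <- as.data.frame(ev)
  cz <- ev[ev$variable == "CoMZ" & ev$kind == "max" & ev$phase == "pre_swing", ]
  expect_equal(nrow(cz), 1L)
  expect_lt(abs(cz$median_offset - (-0.055)), 0.03)
})
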