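test_that("Savitzky-Golay smoothing reproduces cubics and constants", {
  t <- seq(0, 2, by = 0.02)
  cubic <- 2 - 0.5 * t + 3 * t^2 - t^3
  d <- synthetic_derived(t, list(CoMZ = cubic, MPUp = rep(4, length(t))))
  sm <- smooth_derived(d, window = 11)
  interior <- 6:(length(t) - 5)
  expect_equal(sm$data$CoMZ[interior], cubic[interior], tolerance = 1e-9)
  expect_equal(sm$data$MPUp, rep(4, length(t)), tolerance = 1e-9)
})

test_that("smoothing reduces white-noise variance and respects NA masks", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- seq(0, 10, by = 0.02)
    y <- stats::rnorm(length(t))
    sm <- smooth_derived(synthetic_derived(t, list(CoMZ = y)), 11)
    expect_lt(stats::var(sm$data$CoMZ), stats::var(y))
  }
  y2 <- sin(seq(0, 10, by = 0.02))
  y2[100:110] <- NA
  sm2 <- smooth_derived(synthetic_derived(seq(0, 10, by = 0.02), list(CoMZ = y2)), 11)
  expect_true(all(is.na(sm2$data$CoMZ[100:110])))
  expect_false(anyNA(sm2$data$CoMZ[-(95:115)]))
})

test_that("smoothing window preconditions are enforced", {
  t <- seq(0, 1, by = 0.02)
  d <- synthetic_derived(t, list(CoMZ = t))
  expect_error(smooth_derived(d, 10), "odd")
  expect_error(smooth_derived(d, 3), "odd and greater")
  expect_error(smooth_derived(synthetic_derived(t[1:5], list(CoMZ = t[1:5])), 11), "shorter")
})

test_that("central-stride selection keeps a centred window", {
  tl40 <- regular_timeline(40)
  kept <- select_central_strides(tl40, 30)
  expect_equal(nrow(kept), 30L)
  # strides 6..35 of the original: initial contacts 5*T .. 34*T
  expect_equal(kept$initial_contact_loading_response[1], 5 * 1.1)
  expect_equal(kept$initial_contact_loading_response[30], 34 * 1.1)

  tl30 <- regular_timeline(30)
  expect_equal(
    select_central_strides(tl30, 30)$initial_contact_loading_response,
    tl30$initial_contact_loading_response
  )
  # odd surplus: the extra stride is dropped from the start
  tl35 <- regular_timeline(35)
  kept35 <- select_central_strides(tl35, 30)
  expect_equal(kept35$initial_contact_loading_response[1], 3 * 1.1)
  expect_error(select_central_strides(regular_timeline(20), 30), "insufficient")
})

test_that("planted extrema are detected with the anticipation convention", {
  # CoMZ maximum at 55% of each stride; pre-swing onset at 60%
  period <- 1.0
  tl <- regular_timeline(6, period = period, fractions = c(
    mid_stance = 0.10, terminal_stance = 0.30, pre_swing = 0.60,
    initial_swing = 0.70, mid_swing = 0.80, terminal_swing = 0.90
  ))
  t <- seq(0, 6, by = 0.02)
  u <- (t / period) %% 1
  bump <- exp(-((u - 0.55)^2) / (2 * 0.04^2))
  d <- synthetic_derived(t, list(
    CoMZ = 80 + 2 * bump,
    MPUp = rep(3, length(t)) # flat channel
  ))
  cands <- detect_stride_extrema(d, tl)
  cz <- cands[cands$variable == "CoMZ" & cands$kind == "max", ]
  expect_equal(nrow(cz), 6L) # one per stride
  expect_true(all(cz$referenced_phase == "pre_swing"))
  expect_true(all(cz$offset < 0)) # anticipates the phase
  expect_lt(max(abs(cz$offset - (-0.05))), 0.011)
  expect_equal(nrow(cands[cands$variable == "MPUp", ]), 0L) # flat: no events

  # an extremum exactly at a phase onset has offset zero
  bump0 <- exp(-((u - 0.60)^2) / (2 * 0.04^2))
  d0 <- synthetic_derived(t, list(CoMZ = 80 + 2 * bump0))
  c0 <- detect_stride_extrema(d0, tl)
  c0 <- c0[c0$kind == "max", ]
  expect_lt(max(abs(c0$offset)), 0.011)
})

test_that("terminal stance is not used as an event reference by default", {
  period <- 1.0
  tl <- regular_timeline(6, period = period)
  t <- seq(0, 6, by = 0.02)
  u <- (t / period) %% 1
  # extremum at 32%: closest onset is terminal stance (30%), which is
  # excluded, so the event refers to mid stance (10%) or pre-swing (50%)
  d <- synthetic_derived(t, list(
    CoMZ = 80 + exp(-((u - 0.32)^2) / (2 * 0.04^2))
  ))
  cands <- detect_stride_extrema(d, tl)
  expect_false(any(cands$referenced_phase == "terminal_stance"))
  cands2 <- detect_stride_extrema(d, tl, exclude_phases = character(0))
  expect_true(all(
    cands2$referenced_phase[cands2$kind == "max"] == "terminal_stance"
  ))
})

test_that("stride-consistency filter retains events iff they recur enough", {
  mk_cands <- function(k) {
    data.frame(
      variable = "CoMZ", kind = "max", stride_id = seq_len(k),
      time = seq_len(k) * 1.1 + 0.5,
      referenced_phase = "pre_swing", offset = rep(-0.05, k),
      stringsAsFactors = FALSE
    )
  }
  for (k in 20:30) {
    ev <- consolidate_events(mk_cands(k), min_strides = 25, total_strides = 30)
    if (k >= 25) {
      expect_equal(nrow(ev), 1L)
      expect_equal(ev$n_strides_detected, k)
      expect_equal(ev$median_offset, -0.05)
    } else {
      expect_equal(nrow(ev), 0L)
    }
  }
})

test_that("each stride is represented by its candidate nearest the onset", {
  cands <- data.frame(
    variable = "CoMZ", kind = "max",
    stride_id = c(rep(1, 2), 2:25),
    time = 0,
    referenced_phase = "pre_swing",
    offset = c(-0.30, -0.05, rep(-0.05, 24)),
    stringsAsFactors = FALSE
  )
  ev <- consolidate_events(cands, min_strides = 25, total_strides = 30)
  expect_equal(ev$n_strides_detected, 25L)
  expect_equal(ev$median_offset, -0.05) # the -0.30 duplicate is not used
  expect_equal(ev$iqr_offset, 0)
})

test_that("stride-time normalization recovers the mean curve and phases", {
  period <- 1.1
  tl <- regular_timeline(5, period = period)
  t <- seq(0, 5.5, by = 0.02)
  u <- (t / period) %% 1
  y <- sin(2 * pi * u)
  d <- synthetic_derived(t, list(CoMZ = y))
  nz <- normalize_stride_time(d, tl, n_points = 101)
  # identical strides: every stride curve equals the mean curve
  for (s in 1:5) {
    expect_equal(nz$curves$CoMZ[s, ], nz$mean[, "CoMZ"], tolerance = 1e-6)
  }
  expect_equal(
    unname(nz$mean_phase_fractions),
    c(0, 0.10, 0.30, 0.50, 0.60, 0.73, 0.87),
    tolerance = 1e-9
  )
  # a single stride is its own mean
  nz1 <- normalize_stride_time(d, tl[3, ], n_points = 51)
  expect_equal(as.numeric(nz1$curves$CoMZ[1, ]), as.numeric(nz1$mean[, "CoMZ"]))
})
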