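lay <- default_handle_layout()

test_that("single-sensor support puts the centre of pressure on that sensor", {
  f <- matrix(0, 3, 16)
  f[, 3] <- c(0.5, 1, 2) # only sensor 3 loaded, varying force
  d <- compute_derived(fsr_series(c(0, 0.02, 0.04), f), lay)
  expect_equal(d$data$CoMXUp, rep(4.71, 3), tolerance = 1e-12)
  expect_equal(d$data$CoMX, rep(4.71, 3), tolerance = 1e-12)
  expect_equal(d$data$CoMZ, rep(85.22, 3), tolerance = 1e-12)
  expect_true(all(is.na(d$data$CoMXDown))) # no bottom-side force
  expect_equal(d$data$MPDown, rep(0, 3))
})

test_that("uniform loading gives the arithmetic mean of the coordinates", {
  f <- matrix(2.5, 2, 16)
  d <- compute_derived(fsr_series(c(0, 0.02), f), lay)
  # independent oracle: average the coordinates directly
  expect_equal(d$data$CoMXUp[1], mean(lay$x[lay$side == "top"]), tolerance = 1e-12)
  expect_equal(d$data$CoMXDown[1], mean(lay$x[lay$side == "bottom"]), tolerance = 1e-12)
  expect_equal(d$data$CoMX[1], mean(lay$x), tolerance = 1e-12)
  expect_equal(d$data$CoMZ[1], mean(lay$z), tolerance = 1e-12)
  expect_equal(d$data$MPUp[1], 2.5)
  expect_equal(d$data$MPDown[1], 2.5)
})

test_that("zero total force marks centre-of-pressure samples undefined", {
  f <- matrix(1, 3, 16)
  f[2, ] <- 0
  d <- compute_derived(fsr_series(c(0, 0.02, 0.04), f), lay)
  expect_true(all(is.na(as.numeric(d$data[2, c("CoMXUp", "CoMXDown", "CoMX", "CoMZ")]))))
  expect_equal(d$data$MPUp[2], 0)
  expect_equal(d$data$MPDown[2], 0)
  expect_false(anyNA(d$data[c(1, 3), ]))
})

test_that("vectorized variables agree with the naive per-sample oracle", {
  set.seed(42)
  f <- matrix(stats::runif(200 * 16, 0, 5), 200, 16)
  f[sample(length(f), 300)] <- 0 # plenty of idle sensors
  d <- compute_derived(fsr_series(seq(0, by = 0.02, length.out = 200), f), lay)
  oracle <- naive_derived(f, lay)
  for (ch in names(oracle)) {
    expect_equal(d$data[[ch]], oracle[[ch]], tolerance = 1e-9)
  }
})

test_that("centre of pressure is convex and scale-invariant", {
  set.seed(7)
  for (rep_i in 1:50) {
    f <- matrix(stats::runif(16, 0, 3), 1, 16)
    d <- compute_derived(fsr_series(0, f), lay)$data
    top <- lay$side == "top"
    expect_gte(d$CoMXUp, min(lay$x[top]))
    expect_lte(d$CoMXUp, max(lay$x[top]))
    expect_gte(d$CoMXDown, min(lay$x[!top]))
    expect_lte(d$CoMXDown, max(lay$x[!top]))
    expect_gte(d$CoMX, min(lay$x))
    expect_lte(d$CoMX, max(lay$x))
    expect_gte(d$CoMZ, min(lay$z))
    expect_lte(d$CoMZ, max(lay$z))
    c_ <- stats::runif(1, 0.1, 10)
    ds <- compute_derived(fsr_series(0, c_ * f), lay)$data
    expect_equal(ds$CoMX, d$CoMX, tolerance = 1e-12)
    expect_equal(ds$CoMZ, d$CoMZ, tolerance = 1e-12)
    expect_equal(ds$MPUp, c_ * d$MPUp, tolerance = 1e-12)
    expect_equal(ds$MPDown, c_ * d$MPDown, tolerance = 1e-12)
  }
})

test_that("sensor storage order does not affect the variables", {
  set.seed(11)
  f <- matrix(stats::runif(5 * 16, 0, 4), 5, 16)
  t <- seq(0, by = 0.02, length.out = 5)
  d1 <- compute_derived(fsr_series(t, f), lay)
  perm <- sample(16)
  lay2 <- lay[perm, ]
  class(lay2) <- class(lay) # rows shuffled, (id, x, z, side) kept together
  d2 <- compute_derived(fsr_series(t, f), lay2)
  expect_equal(d1$data, d2$data, tolerance = 1e-12)
})

test_that("channel-count mismatch is a configuration error", {
  expect_error(fsr_series(c(0, 0.02), matrix(1, 2, 15)), "16 channels")
})

test_that("differentiation matches closed forms", {
  t <- seq(0, 2, by = 0.02)
  d <- synthetic_derived(t, list(
    CoMZ = rep(80, length(t)),
    CoMX = 3 * t,
    MPUp = sin(2 * pi * t)
  ))
  dd <- differentiate(d)
  expect_equal(dd$data$dCoMZ, rep(0, length(t)))
  interior <- 2:(length(t) - 1)
  expect_equal(dd$data$dCoMX[interior], rep(3, length(interior)),
    tolerance = 1e-9
  )
  # central difference of a sinusoid: analytic derivative within O(h^2)
  expect_equal(dd$data$dMPUp[interior], (2 * pi * cos(2 * pi * t))[interior],
    tolerance = 3e-3
  )
  expect_error(
    differentiate(synthetic_derived(c(0, 0.02), list(CoMZ = c(1, 2)))),
    "3 samples"
  )
})
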