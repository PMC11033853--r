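test_that("Hann window identities hold on the analysis grid", {
  expect_equal(hann_weight(0, 1), 1)
  expect_equal(hann_weight(0.5, 1), 0)
  expect_equal(hann_weight(-0.5, 1), 0)
  expect_error(hann_weight(0.6, 1), "w/2")
  s <- seq(-0.5, 0.5, by = 1 / 500)
  H <- hann_weight(s, 1)
  expect_equal(sum(H) / 500, 1 / 2, tolerance = 1e-12)        # int H  = w/2
  expect_equal(sum(H^2) / 500, 3 / 8, tolerance = 1e-12)      # int H^2 = 3w/8
})

test_that("power density vanishes for a zero signal and scales quadratically", {
  y <- emg_signal(numeric(2500), fs = 500)
  p <- power_density(y, c(6, 50, 130), c(1, 2, 3))
  expect_true(all(p == 0))
  set.seed(1)
  v <- rnorm(2500, 0, 0.1)
  p1 <- power_density(v, 2:200, 2.5)
  p2 <- power_density(2 * v, 2:200, 2.5)
  expect_equal(p2, 4 * p1, tolerance = 1e-12)
})

test_that("a unit sinusoid gives the closed-form Hann power a^2 w / 16", {
  t <- (0:2499) / 500
  for (f0 in c(20, 50, 121)) {
    y <- sin(2 * pi * f0 * t)
    p <- power_density(y, f0, 2.5)
    expect_equal(p, 1 / 16, tolerance = 0.05)
  }
})

test_that("band power is the time integral of the density", {
  t <- (0:2499) / 500
  y <- 0.5 * sin(2 * pi * 40 * t)
  params <- spectral_params()
  P <- band_power(y, 40, T_eval = 4, params = params)
  p_mid <- power_density(y, 40, 2, params)
  # stationary: P = T * p up to the zero-padded half-window at each edge
  expect_equal(P, 4 * p_mid, tolerance = 0.05)
  # additivity over adjacent windows via the hop-grid trapezoid
  P1 <- band_power(y, 40, T_eval = 2, params = params)
  expect_lt(abs(P - P1 - 2 * p_mid) / P, 0.03)
})

test_that("system output matches the Hann leakage closed form 3 a^2 / 32", {
  t <- (0:2999) / 500
  y <- emg_signal(sin(2 * pi * 50 * t), fs = 500, kind = "estimated")
  z <- system_output(y, 50)$z
  expect_equal(z, 3 / 32, tolerance = 0.05)
  expect_equal(system_output(emg_signal(numeric(3000), 500))$z, 0)
})

test_that("system output is exactly quadratic in the signal amplitude", {
  set.seed(2)
  v <- rnorm(3000, 0, 0.05)
  z1 <- system_output(emg_signal(v, 500))$z
  z3 <- system_output(emg_signal(3 * v, 500))$z
  expect_equal(z3, 9 * z1, tolerance = 1e-12)
})

test_that("out-of-band content contributes almost nothing", {
  t <- (0:2999) / 500
  z_dc <- system_output(emg_signal(rep(1, 3000), 500))$z
  z_in <- system_output(emg_signal(sin(2 * pi * 50 * t), 500))$z
  expect_lt(z_dc / z_in, 0.01)
})

test_that("halving the hop changes the output by <1%", {
  set.seed(3)
  v <- rnorm(3000, 0, 0.05)
  z1 <- system_output(emg_signal(v, 500), params = spectral_params(hop = 0.01))$z
  z2 <- system_output(emg_signal(v, 500), params = spectral_params(hop = 0.005))$z
  expect_lt(abs(z1 - z2) / z1, 0.01)
})

test_that("white-noise output scales with the noise variance", {
  zs <- sapply(1:20, function(s) {
    set.seed(s)
    system_output(emg_signal(rnorm(3000, 0, 0.02), 500))$z
  })
  zs2 <- sapply(1:20, function(s) {
    set.seed(100 + s)
    system_output(emg_signal(rnorm(3000, 0, 0.04), 500))$z
  })
  expect_equal(mean(zs2) / mean(zs), 4, tolerance = 0.1)
  # and matches the analytic expectation 199 * sigma^2 * 3 / (8 fs)
  expect_equal(mean(zs), 199 * 0.02^2 * 3 / (8 * 500), tolerance = 0.05)
})

test_that("constructor validates the band against Nyquist", {
  expect_error(spectral_params(fs = 300, band = 2:200), "Nyquist")
  expect_error(spectral_params(window_w = 6, T_eval = 5), "T_eval")
  expect_error(system_output(emg_signal(numeric(100), 500)), "horizon")
})
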