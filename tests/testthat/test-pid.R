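test_that("the PID step reproduces the published-gain arithmetic", {
  g <- pid_gains()
  # zero history: raw 0, clamped to the lowest valid frequency
  u0 <- pid_step(c(0, 0, 0), g)
  expect_equal(as.numeric(u0), 10)
  expect_equal(attr(u0, "raw"), 0)
  # single step with e = 1e-3: Kp e + Ki e dt = 1 + 100/3
  u1 <- pid_step(1e-3, g)
  expect_equal(as.numeric(u1), 1 + 1e5 * 1e-3 / 3, tolerance = 1e-12)
  # constant error: the integral term grows linearly with the history length
  raws <- sapply(1:6, function(m) attr(pid_step(rep(2e-3, m), g), "raw"))
  expect_equal(diff(raws, differences = 2), rep(0, 4), tolerance = 1e-9)
  expect_error(pid_step(c(1, NA), g), "finite")
})

test_that("the output is always clamped to the stimulation range", {
  g <- pid_gains()
  expect_equal(as.numeric(pid_step(10, g)), 200)
  expect_equal(as.numeric(pid_step(-10, g)), 10)
})

# The linear demonstration plants below work on a power scale of order 1
# rather than the mV^2 scale the published gains are matched to; the loop is
# run with the gains at proportionally reduced magnitude, under which it
# converges to the unique fixed point of any strictly decreasing plant.
gains_o1 <- function() pid_gains(Kp = 1, Ki = 100, Kd = 5)

test_that("the loop recovers the fixed point of a linear plant", {
  # z(u) = 2 - 0.01 u, target 0.7 -> u* = 130
  plant <- function(u) 2 - 0.01 * u
  tr <- run_closed_loop(0.7, plant, gains_o1(), noise_band = 1e-3)
  expect_equal(nrow(tr), 31)
  expect_lt(abs(tail(tr$u_hz, 1) - 130), 2)
  expect_true(attr(tr, "converged"))
  expect_lt(attr(tr, "settling_time"), 10)
  expect_true(all(tr$u_hz >= 10 & tr$u_hz <= 200))
})

test_that("other linear-plant fixed points are recovered too", {
  for (ustar in c(60, 100, 170)) {
    plant <- function(u) 1.5 - 0.008 * u
    tr <- run_closed_loop(1.5 - 0.008 * ustar, plant, gains_o1(),
                          noise_band = 1e-3)
    expect_lt(abs(tail(tr$u_hz, 1) - ustar), 2)
  }
})

test_that("a self-consistent target keeps the loop finite from the start", {
  plant <- function(u) 1 - 0.002 * u
  tr <- run_closed_loop(plant(10), plant, gains_o1(), noise_band = 1e-3)
  expect_equal(tr$e[1], 0)
  expect_true(all(is.finite(tr$u_hz)))
  expect_equal(nrow(tr), 31)
})

test_that("plant failures abort with a diagnostic", {
  bad <- function(u) NaN
  expect_error(run_closed_loop(0.5, bad, gains_o1(), noise_band = 1e-3),
               "non-finite")
})

test_that("a pinned seed makes stochastic closed loops reproducible", {
  plant <- function(u) 1 - 0.004 * u + rnorm(1, 0, 1e-3)
  t1 <- run_closed_loop(0.5, plant, gains_o1(), noise_band = 5e-3, seed = 9)
  t2 <- run_closed_loop(0.5, plant, gains_o1(), noise_band = 5e-3, seed = 9)
  expect_identical(t1$z, t2$z)
  expect_identical(t1$u_hz, t2$u_hz)
})

test_that("multi-target sweeps order steady states inversely to target power", {
  plant <- function(u) 2 - 0.01 * u
  targets <- lapply(c(120, 130, 140), function(u) plant(u))
  trs <- multi_target_sweep(targets, plant, gains_o1(), noise_band = 1e-3)
  finals <- sapply(trs, function(tr) tail(tr$u_hz, 1))
  expect_equal(finals, c(120, 130, 140), tolerance = 0.02)
  # higher power target -> lower frequency
  expect_true(all(diff(sapply(targets, identity)) < 0))
  expect_true(all(diff(finals) > 0))
})

test_that("the model plant rejects frequencies outside the biomarker range", {
  fx <- get_fixtures()
  plant <- make_model_plant(fx$biomarker, fx$config$vim_network,
                            spectral_params(T_eval = 2))
  expect_error(plant(5), "\\[10, 200\\]")
  expect_error(plant(220), "\\[10, 200\\]")
  z1 <- plant(130, seed = 3)
  z2 <- plant(130, seed = 3)
  expect_identical(z1, z2)
  expect_gt(z1, 0)
})

test_that("doubling plant noise widens errors but not the mean steady state", {
  mk <- function(sd) function(u) 1 - 0.004 * u + rnorm(1, 0, sd)
  finals <- function(sd, seeds) sapply(seeds, function(s) {
    tr <- run_closed_loop(1 - 0.004 * 130, mk(sd), gains_o1(),
                          noise_band = 3 * sd, seed = s)
    tail(tr$u_hz, 1)
  })
  f1 <- finals(5e-4, 1:20)
  f2 <- finals(1e-3, 21:40)
  # doubling the noise inflates the error spread but leaves the mean
  # steady-state frequency within the (larger) noise band in frequency units
  expect_lt(abs(mean(f1) - mean(f2)), 3 * 1e-3 / 0.004)
  expect_gt(sd(f2), sd(f1) / 4)
})
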