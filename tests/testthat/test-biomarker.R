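test_that("standardization has the stated algebraic properties", {
  x <- rate_signal(20 + 10 * abs(sin(seq(0, 40, by = 0.02))), dt = 2)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # affine invariance under own statistics
  z2 <- standardize(3.7 * x$values + 11)
  expect_equal(as.numeric(z), as.numeric(z2), tolerance = 1e-10)
  expect_error(standardize(rep(5, 100)), "sd is zero")
})

test_that("a noiseless degree-5 relationship is recovered exactly", {
  set.seed(1)
  x <- rate_signal(30 + 15 * abs(sin(seq(0, 60, by = 0.012))), dt = 2)
  z <- as.numeric(standardize(x))
  y <- emg_signal(0.02 - 0.1 * z + 0.05 * z^2 - 0.01 * z^3 +
                    0.004 * z^4 + 0.002 * z^5, fs = 500)
  fit <- fit_biomarker(list(`130` = x), list(`130` = y), order = 5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)),
               c(0.02, -0.1, 0.05, -0.01, 0.004, 0.002), tolerance = 1e-6)
  # prediction without noise reproduces the targets
  pred <- predict(fit, x, add_noise = FALSE)
  expect_equal(pred$values, y$values, tolerance = 1e-8)
  expect_equal(pred$kind, "estimated")
})

test_that("degenerate training inputs are rejected", {
  flat <- rate_signal(rep(25, 2500), dt = 2)
  y <- emg_signal(rnorm(2500, 0, 0.01), fs = 500)
  expect_error(fit_biomarker(list(a = flat), list(a = y), order = 5))
  expect_error(fit_biomarker(list(a = flat), list(b = y), order = 5),
               "same frequencies")
})

test_that("a constant-polynomial estimator returns its intercept", {
  x <- rate_signal(20 + 10 * abs(sin(seq(0, 40, by = 0.02))), dt = 2)
  y <- emg_signal(rep(0.25, length(x$values)), fs = 500)
  fit <- fit_biomarker(list(a = x), list(a = y), order = 3)
  pred <- predict(fit, x, add_noise = FALSE)
  expect_equal(pred$values, rep(0.25, length(x$values)), tolerance = 1e-10)
})

test_that("the noiseless estimate is a memoryless map of the rate", {
  fx <- get_fixtures()
  est <- fx$biomarker
  x <- fx$runs[["130"]]$vim_rate
  xr <- dbsloop:::resample_rate(x, est$fs)
  set.seed(2)
  perm <- sample(length(xr$values))
  y1 <- predict(est, xr$values, add_noise = FALSE)$values
  y2 <- predict(est, xr$values[perm], add_noise = FALSE)$values
  expect_equal(y2, y1[perm], tolerance = 1e-12)
})

test_that("training R-squared rises monotonically with order to a knee", {
  set.seed(3)
  x <- rate_signal(30 + 15 * abs(sin(seq(0, 60, by = 0.012))), dt = 2)
  z <- as.numeric(standardize(x))
  y <- emg_signal(0.1 * z - 0.03 * z^3 + 0.01 * z^5, fs = 500)
  fit <- fit_biomarker(list(a = x), list(a = y), order = 8)
  curve <- order_selection_curve(fit, max_order = 8)
  expect_true(all(diff(curve$r_squared) >= -1e-10))
  expect_equal(curve$r_squared[5], 1, tolerance = 1e-10)
  expect_equal(attr(curve, "knee"), 5L)
  # nested-model property on real pipeline data
  fx <- get_fixtures()
  curve2 <- order_selection_curve(fx$biomarker, max_order = 5)
  expect_true(all(diff(curve2$r_squared) >= -1e-10))
})

test_that("training R-squared is invariant to affine rescaling of the rate", {
  fx <- get_fixtures()
  rates <- lapply(fx$runs[c("10", "130")], `[[`, "vim_rate")
  emgs <- lapply(fx$runs[c("10", "130")], `[[`, "emg")
  f1 <- fit_biomarker(rates, emgs, order = 5)
  rates2 <- lapply(rates, function(r) rate_signal(2.5 * r$values + 7, r$dt))
  f2 <- fit_biomarker(rates2, emgs, order = 5)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-8)
})

test_that("the estimator serializes to JSON and back losslessly", {
  fx <- get_fixtures()
  est <- fx$biomarker
  path <- tempfile(fileext = ".json")
  write_biomarker_json(est, path)
  back <- read_biomarker_json(path)
  x <- fx$runs[["10"]]$vim_rate
  expect_equal(predict(back, x, add_noise = FALSE)$values,
               predict(est, x, add_noise = FALSE)$values, tolerance = 1e-12)
  expect_equal(back$coefficients, est$coefficients, tolerance = 1e-12)
  expect_equal(back$standardization$mean, est$standardization$mean)
})

test_that("inputs far outside the training range trigger a warning", {
  fx <- get_fixtures()
  est <- fx$biomarker
  extreme <- rate_signal(rep(c(0, 4000), 50), dt = 2)
  expect_warning(predict(est, extreme, add_noise = FALSE), "training range")
})

test_that("model methods expose the fit in the usual R idiom", {
  fx <- get_fixtures()
  est <- fx$biomarker
  expect_output(print(est), "order-5 polynomial")
  expect_output(print(summary(est)), "standardization")
  expect_length(coef(est), est$order + 1)
  expect_equal(length(residuals(est)), est$n_obs)
  expect_equal(fitted(est) + residuals(est), est$training$y, tolerance = 1e-9)
  sims <- simulate(est, nsim = 2, seed = 1, x = fx$runs[["10"]]$vim_rate)
  expect_equal(ncol(sims), 2)
})
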