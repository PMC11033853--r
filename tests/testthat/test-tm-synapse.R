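# Independent oracle: iterate the per-pulse depression recursion
#   r_{n+1} = (r_n - U r_n) exp(-D / tau_dep) + 1 - exp(-D / tau_dep)
# to convergence, giving the steady-state resources before each pulse.
depression_steady_state <- function(U, tau_dep, interval) {
  r <- 1
  for (i in 1:5000) {
    r_new <- (r - U * r) * exp(-interval / tau_dep) +
      1 - exp(-interval / tau_dep)
    if (abs(r_new - r) < 1e-14) break
    r <- r_new
  }
  r
}

test_that("the first event from rest releases exactly U * gain", {
  for (U in c(0.1, 0.2, 0.9)) {
    p <- tm_params(U = U, tau_fac = 0, tau_dep = 100, tau_syn = 10, gain = 3)
    i <- tm_current(0, p, dt = 0.1, duration = 100)
    expect_equal(i[1], U * 3)
  }
  p_inh <- tm_params(U = 0.5, gain = 2, sign = -1)
  expect_equal(tm_current(0, p_inh, dt = 0.1, duration = 10)[1], -1)
})

test_that("periodic depression matches the per-pulse recursion oracle", {
  cases <- list(c(U = 0.2, tau = 100, f = 100), c(U = 0.2, tau = 100, f = 10),
                c(U = 0.5, tau = 250, f = 130), c(U = 0.05, tau = 40, f = 200))
  for (cs in cases) {
    D <- 1000 / cs[["f"]]
    p <- tm_params(U = cs[["U"]], tau_fac = 0, tau_dep = cs[["tau"]])
    st <- dbsloop:::tm_event_states(seq(0, 5000, by = D), p)
    expect_equal(tail(st$r_before, 1),
                 depression_steady_state(cs[["U"]], cs[["tau"]], D),
                 tolerance = 1e-8)
  }
})

test_that("empty trains and zero gain give identically zero current", {
  p <- tm_params()
  expect_equal(tm_current(numeric(0), p, dt = 0.1, duration = 100),
               numeric(1000))
  p0 <- tm_params(gain = 0)
  expect_equal(tm_current(pulse_train(100, 500), p0, dt = 0.1, duration = 500),
               numeric(5000))
  expect_error(tm_current(0, p, dt = -1, duration = 10), "dt")
})

test_that("pooled currents are the sum over independent synapses", {
  p <- tm_params(U = 0.3, gain = 2)
  one <- tm_current(5, p, dt = 0.1, duration = 50)
  two <- pool_tm_currents(list(5, 5), p, dt = 0.1, duration = 50)
  expect_equal(two, 2 * one)
  expect_equal(pool_tm_currents(list(), p, dt = 0.1, duration = 50),
               numeric(500))
})

test_that("per-synapse state differs from a single merged synapse", {
  # two interleaved trains through separate synapses vs all events through one
  p <- tm_params(U = 0.4, tau_dep = 80, tau_syn = 5, gain = 1)
  a <- seq(0, 400, by = 40)
  b <- seq(20, 400, by = 40)
  pooled <- pool_tm_currents(list(a, b), p, dt = 0.1, duration = 500)
  merged <- tm_current(sort(c(a, b)), p, dt = 0.1, duration = 500)
  expect_gt(max(abs(pooled - merged)), 1e-3)
})

test_that("resources stay within [0, 1] on randomized event trains", {
  set.seed(7)
  for (i in 1:20) {
    times <- sort(runif(50, 0, 1000))
    p <- tm_params(U = runif(1, 0.05, 0.95), tau_fac = sample(c(0, 50), 1),
                   tau_dep = runif(1, 20, 400))
    st <- dbsloop:::tm_event_states(times, p)
    expect_true(all(st$r_avail >= 0 & st$r_avail <= 1))
    expect_true(all(st$u_rel >= 0 & st$u_rel <= 1))
  }
})

test_that("steady-state release amplitude is non-increasing in frequency", {
  p <- tm_params(U = 0.2, tau_fac = 0, tau_dep = 100, gain = 1)
  amps <- sapply(c(10, 50, 100, 200), function(f) {
    st <- dbsloop:::tm_event_states(seq(0, 5000, by = 1000 / f), p)
    tail(abs(st$jump), 1)
  })
  expect_true(all(diff(amps) <= 1e-12))
})

test_that("time rescaling leaves event-indexed states unchanged", {
  times <- c(0, 8, 25, 26, 90, 200)
  p1 <- tm_params(U = 0.3, tau_fac = 30, tau_dep = 120, tau_syn = 10)
  p2 <- tm_params(U = 0.3, tau_fac = 60, tau_dep = 240, tau_syn = 20)
  s1 <- dbsloop:::tm_event_states(times, p1)
  s2 <- dbsloop:::tm_event_states(2 * times, p2)
  expect_equal(s1$u_rel, s2$u_rel)
  expect_equal(s1$r_avail, s2$r_avail)
  expect_equal(s1$jump, s2$jump)
})
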