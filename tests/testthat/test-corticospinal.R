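test_that("Poisson thinning reproduces the expected counts and distribution", {
  rate <- rate_signal(rep(20, 1e5), dt = 0.1)     # 20 Hz for 10 s
  sp <- poisson_spikes(rate, n_neurons = 100, seed = 3)
  counts <- lengths(sp$trains)
  expect_equal(mean(counts), 200, tolerance = 0.05)
  # chi-squared goodness of fit of the per-neuron counts against Poisson(200)
  sp2 <- poisson_spikes(rate_signal(rep(50, 2000), dt = 0.1), 1e4, seed = 4)
  k <- lengths(sp2$trains)                         # Poisson(10) counts
  brk <- c(-Inf, 5:15, Inf)
  obs <- table(cut(k, brk))
  pr <- diff(ppois(c(-Inf, 5:15, Inf), 10))
  pval <- chisq.test(as.numeric(obs), p = pr)$p.value
  expect_gt(pval, 0.01)
  # reproducibility and the zero-rate case
  sp_rep <- poisson_spikes(rate, n_neurons = 100, seed = 3)
  expect_identical(sp$trains, sp_rep$trains)
  expect_equal(sum(lengths(poisson_spikes(rate_signal(rep(0, 100), 0.1),
                                          5)$trains)), 0)
})

test_that("over-coarse bins for the Poisson approximation are rejected", {
  expect_error(poisson_spikes(rate_signal(rep(400, 100), dt = 1), 3),
               "smaller dt")
})

test_that("LIF interspike interval matches the closed form within 2%", {
  # V_inf = EL + R*I = -25 mV; ISI = t_ref + tau_V ln((Vinf-Vr)/(Vinf-Vth))
  sp <- lif_spikes(matrix(40, 50000, 2), m1_params(), dt = 0.1)
  isi <- diff(sp$trains[[1]])
  expect_equal(mean(isi), 1 + 10 * log(65 / 10), tolerance = 0.02)
  # subthreshold drive (V_inf = -45 mV < V_th) and no drive give no spikes
  expect_equal(sum(lengths(lif_spikes(matrix(20, 20000, 1),
                                      m1_params())$trains)), 0)
  expect_equal(sum(lengths(lif_spikes(matrix(0, 20000, 1),
                                      m1_params())$trains)), 0)
})

test_that("M1 spikes respect the absolute refractory period", {
  sp <- lif_spikes(matrix(100, 20000, 3), m1_params(), dt = 0.1)
  for (tr in sp$trains) expect_true(all(diff(tr) >= m1_params()$t_ref - 1e-9))
})

test_that("motoneuron PSC kernel has onset C after the delay and tau_i decay", {
  mp <- motoneuron_params()
  m1 <- spike_trains(list(c(0)), duration = 100, population = "m1")
  conn <- matrix(1L, nrow = 1, ncol = 1)
  I <- motoneuron_input_current(m1, conn, mp, dt = 0.1, duration = 100)
  expect_equal(I[101, 1], mp$C)                       # t = 10 ms: onset
  expect_equal(I[301, 1], mp$C * exp(-1), tolerance = 1e-6)  # one e-fold later
  expect_true(all(I[1:100, 1] == 0))
  # superposition of two simultaneous inputs
  m1b <- spike_trains(list(c(0), c(0)), duration = 100, population = "m1")
  connb <- matrix(c(1L, 2L), nrow = 1)
  Ib <- motoneuron_input_current(m1b, connb, mp, dt = 0.1, duration = 100)
  expect_equal(Ib[, 1], 2 * I[, 1])
  # no spikes -> zero current
  empty <- spike_trains(list(numeric(0)), duration = 50, population = "m1")
  expect_true(all(motoneuron_input_current(empty, conn, mp, dt = 0.1,
                                           duration = 50) == 0))
})

test_that("motoneuron membrane follows the spike-response closed forms", {
  mp <- motoneuron_params(Vth_range = c(10, 10))
  # constant current: V -> Rm * I; threshold 10 mV crossed iff I > 10/36
  quiet <- simulate_motoneurons(matrix(0.25, 30000, 1), mp, seed = 1)
  expect_equal(sum(lengths(quiet$trains)), 0)
  firing <- simulate_motoneurons(matrix(0.35, 30000, 1), mp, seed = 1)
  expect_gt(sum(lengths(firing$trains)), 3)
  # recursive convolution vs exact quadrature of the piecewise-constant
  # current (closed-form integral over each bin)
  set.seed(5)
  dt <- 0.02
  I <- abs(rnorm(5000, 0.2, 0.1))
  dec <- exp(-dt / mp$tau_m)
  J_rec <- 0; J_exact <- 0
  w_exact <- mp$tau_m * (1 - dec)
  for (t in seq_along(I)) {
    J_rec <- J_rec * dec + dt * I[t]
    J_exact <- J_exact * dec + w_exact * I[t]
  }
  expect_equal(J_rec, J_exact, tolerance = 0.005)
})

test_that("thresholds are drawn reproducibly and in range", {
  mp <- motoneuron_params()
  a <- simulate_motoneurons(matrix(0.1, 100, mp$N_m), mp, seed = 9)
  b <- simulate_motoneurons(matrix(0.1, 100, mp$N_m), mp, seed = 9)
  expect_identical(attr(a, "thresholds"), attr(b, "thresholds"))
  expect_true(all(attr(a, "thresholds") >= 5 & attr(a, "thresholds") <= 15))
})

test_that("connectivity draws fan_in distinct inputs, reproducibly", {
  mp <- motoneuron_params(N_m = 12, fan_in = 7)
  A <- motoneuron_connectivity(mp, n_m1 = 20, seed = 2)
  expect_equal(dim(A), c(12, 7))
  expect_true(all(apply(A, 1, function(r) length(unique(r)) == 7)))
  expect_identical(A, motoneuron_connectivity(mp, n_m1 = 20, seed = 2))
  expect_error(motoneuron_connectivity(motoneuron_params(fan_in = 30), 20),
               "fan_in")
})

test_that("DBS-OFF motoneuron rates sit in the physiological 5-50 Hz band", {
  sim <- run_full_pipeline(0, duration = 5000, config = dbs_config(),
                           seed = 11)
  med <- median(firing_rates(sim$motoneuron_spikes))
  expect_gt(med, 5)
  expect_lt(med, 50)
})
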