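#' Spinal motoneuron parameters
#'
#' The motoneuron membrane follows a spike-response formulation: after its
#' last spike at `t_sp`, the potential is the sum of a reset transient
#' `V0 * exp(-(t - t_sp) / tau_p)` and a recovery-gated convolution of the
#' synaptic current, `(Rm / tau_m) * (1 - exp(-(t - t_sp) / tau_r)) *
#' integral( exp(-s / tau_m) I(t - s) ds )`. Voltages here are relative to
#' rest (thresholds are positive, the reset is negative), a different
#' convention from the absolute-scale M1 membrane; both are kept as stated in
#' the source model.
#'
#' @param V0 Reset potential (mV).
#' @param Rm Input resistance (MOhm).
#' @param tau_p Refractory time constant (ms).
#' @param tau_m Passive membrane time constant (ms).
#' @param tau_r Recovery time constant (ms).
#' @param Vth_range Per-neuron firing-threshold interval (mV); thresholds are
#'   drawn uniformly, one per motoneuron.
#' @param N_m Population size.
#' @param fan_in Number of M1 neurons each motoneuron connects to.
#' @param C PSC scale of one M1 spike (nA).
#' @param td_cm M1-to-motoneuron conduction delay (ms).
#' @param tau_i PSC decay time constant (ms).
#' @return An object of class `motoneuron_params`.
#' @export
motoneuron_params <- function(V0 = -22, Rm = 36, tau_p = 2, tau_m = 4,
                              tau_r = 100, Vth_range = c(5, 15), N_m = 120,
                              fan_in = 70, C = 0.1, td_cm = 10, tau_i = 20) {
  if (Vth_range[1] <= V0) stop("thresholds must exceed the reset potential",
                               call. = FALSE)
  structure(list(V0 = V0, Rm = Rm, tau_p = tau_p, tau_m = tau_m,
                 tau_r = tau_r, Vth_range = Vth_range, N_m = N_m,
                 fan_in = fan_in, C = C, td_cm = td_cm, tau_i = tau_i),
            class = "motoneuron_params")
}

#' Random M1-to-motoneuron connectivity
#'
#' Each motoneuron connects to `fan_in` distinct M1 neurons chosen uniformly
#' without replacement; the wiring is fixed for a simulation run.
#'
#' @param params A [motoneuron_params] object.
#' @param n_m1 Number of M1 neurons available.
#' @param seed Optional integer seed.
#' @return Integer matrix `N_m x fan_in` of M1 indices.
#' @export
motoneuron_connectivity <- function(params, n_m1, seed = NULL) {
  if (params$fan_in > n_m1)
    stop("`fan_in` cannot exceed the number of M1 neurons", call. = FALSE)
  with_seed(seed, t(vapply(seq_len(params$N_m),
                           function(j) sort(sample.int(n_m1, params$fan_in)),
                           integer(params$fan_in))))
}

#' Post-synaptic currents into the motoneuron pool
#'
#' Every spike of a connected M1 neuron contributes a delayed exponential PSC
#' `C * exp(-(t - td_cm - k) / tau_i)` for `t >= k + td_cm`; contributions
#' add linearly over the `fan_in` inputs.
#'
#' @param m1_spikes A [spike_trains] object for the M1 population.
#' @param connectivity Integer matrix from [motoneuron_connectivity()].
#' @param params A [motoneuron_params] object.
#' @param dt Sample interval (ms).
#' @param duration Span (ms); defaults to the spike-train duration.
#' @return Numeric matrix `n_steps x N_m` of currents (nA).
#' @export
motoneuron_input_current <- function(m1_spikes, connectivity, params,
                                     dt = 0.1, duration = m1_spikes$duration) {
  stopifnot(inherits(m1_spikes, "spike_trains"))
  n <- round(duration / dt)
  n_m1 <- length(m1_spikes$trains)
  # spike counts per (step, m1 neuron), shifted by the conduction delay
  counts <- matrix(0, nrow = n, ncol = n_m1)
  d_steps <- as.integer(round(params$td_cm / dt))
  for (i in seq_len(n_m1)) {
    tr <- m1_spikes$trains[[i]]
    if (!length(tr)) next
    idx <- as.integer(floor(tr / dt + 1e-9)) + 1L + d_steps
    idx <- idx[idx <= n]
    for (k in idx) counts[k, i] <- counts[k, i] + 1
  }
  # route to motoneurons and apply the exponential kernel recursively
  A <- matrix(0, nrow = n_m1, ncol = nrow(connectivity))
  for (j in seq_len(nrow(connectivity))) A[connectivity[j, ], j] <- 1
  inp <- counts %*% A
  decay <- exp(-dt / params$tau_i)
  out <- matrix(0, nrow = n, ncol = ncol(inp))
  for (j in seq_len(ncol(inp)))
    out[, j] <- stats::filter(params$C * inp[, j], decay, method = "recursive")
  out
}

#' Simulate the motoneuron pool
#'
#' Integrates the spike-response membrane with the exact exponential
#' recursion `J(t + dt) = exp(-dt / tau_m) * J(t) + dt * I(t + dt)` for the
#' current convolution. On reaching its threshold a neuron spikes, the
#' potential is reset to `V0` and the integration restarts (J is cleared).
#' Per-neuron thresholds are drawn uniformly from `Vth_range` under `seed`.
#'
#' @param currents Numeric matrix `n_steps x N_m` of input currents (nA),
#'   from [motoneuron_input_current()].
#' @param params A [motoneuron_params] object.
#' @param seed Optional integer seed for the threshold draws.
#' @param dt Sample interval of `currents` (ms).
#' @return A [spike_trains] object with attribute `"thresholds"`.
#' @export
simulate_motoneurons <- function(currents, params, seed = NULL, dt = 0.1) {
  currents <- as.matrix(currents)
  n <- nrow(currents); m <- ncol(currents)
  vth <- with_seed(seed, runif(m, params$Vth_range[1], params$Vth_range[2]))
  dec_m <- exp(-dt / params$tau_m)
  J <- numeric(m)             # convolution state (nA ms)
  elapsed <- rep(1e9, m)      # time since last spike (ms)
  sp_step <- vector("list", n); any_sp <- FALSE
  rm_tm <- params$Rm / params$tau_m
  for (t in seq_len(n)) {
    J <- J * dec_m + dt * currents[t, ]
    elapsed <- elapsed + dt
    V <- params$V0 * exp(-elapsed / params$tau_p) +
      rm_tm * (1 - exp(-elapsed / params$tau_r)) * J
    fired <- V >= vth
    if (any(fired)) {
      sp_step[[t]] <- which(fired)
      J[fired] <- 0
      elapsed[fired] <- 0
      any_sp <- TRUE
    }
  }
  trains <- rep(list(numeric(0)), m)
  if (any_sp) {
    steps <- rep.int(seq_len(n), lengths(sp_step))
    ids <- unlist(sp_step, use.names = FALSE)
    trains <- split((steps - 1) * dt, factor(ids, levels = seq_len(m)))
    trains <- lapply(trains, as.numeric)
  }
  out <- spike_trains(trains, duration = n * dt, population = "motoneuron")
  attr(out, "thresholds") <- vth
  out
}
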