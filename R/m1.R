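#' Poisson spike generation from a rate signal
#'
#' Treats a firing-rate trace as the time-varying intensity of a Poisson
#' process and draws spikes by per-bin thinning: a spike occurs in a bin with
#' probability `rate * dt / 1000`. The bin width must keep that probability
#' small for the thinning approximation to hold.
#'
#' @param rate A [rate_signal].
#' @param n_neurons Number of independent realizations to draw.
#' @param seed Optional integer seed (draws are bit-reproducible given it).
#' @return A [spike_trains] object with spike times on the rate grid.
#' @export
poisson_spikes <- function(rate, n_neurons, seed = NULL) {
  stopifnot(inherits(rate, "rate_signal"))
  p <- rate$values * rate$dt / 1000
  if (any(p > 0.3))
    stop("rate * dt / 1000 exceeds 0.3 in some bin; use a smaller dt",
         call. = FALSE)
  grid <- (seq_along(p) - 1) * rate$dt
  with_seed(seed, {
    trains <- lapply(seq_len(n_neurons), function(i)
      grid[runif(length(p)) < p])
    spike_trains(trains, duration = rate$duration, population = "poisson")
  })
}

#' M1 leaky integrate-and-fire population parameters
#'
#' The motor-cortex population is `N_c` independent LIF neurons obeying
#' `tau_V * dV/dt = -(V - EL) + R * Isyn` with threshold/reset spiking and an
#' absolute refractory period.
#'
#' @param EL Equilibrium potential (mV).
#' @param R Membrane resistance (MOhm).
#' @param tau_V Membrane time constant (ms).
#' @param V_th Spike threshold (mV).
#' @param V_reset Reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param N_c Population size.
#' @return An object of class `m1_params`.
#' @export
m1_params <- function(EL = -65, R = 1, tau_V = 10, V_th = -35, V_reset = -90,
                      t_ref = 1, N_c = 150) {
  if (V_reset >= V_th) stop("`V_reset` must be below `V_th`", call. = FALSE)
  if (t_ref < 0 || N_c < 1) stop("invalid `t_ref` or `N_c`", call. = FALSE)
  structure(list(EL = EL, R = R, tau_V = tau_V, V_th = V_th,
                 V_reset = V_reset, t_ref = t_ref, N_c = N_c),
            class = "m1_params")
}

#' LIF population spikes from synaptic current traces
#'
#' Integrates one LIF neuron per column of `I` with exponential-Euler steps.
#' Between spikes `V` relaxes toward `EL + R * I(t)`; on threshold crossing a
#' spike is recorded, `V` is reset and held for the refractory period.
#'
#' @param I Numeric matrix of synaptic currents (nA), `n_steps x n_neurons`
#'   (a vector is treated as one neuron).
#' @param params An [m1_params] object (its `N_c` is ignored here; the number
#'   of columns of `I` decides the population size).
#' @param dt Integration step (ms).
#' @return A [spike_trains] object.
#' @export
lif_spikes <- function(I, params, dt = 0.1) {
  I <- as.matrix(I)
  n <- nrow(I); m <- ncol(I)
  decay <- exp(-dt / params$tau_V)
  ref_steps <- as.integer(round(params$t_ref / dt))
  V <- rep(params$EL, m)
  refr <- integer(m)
  sp_step <- vector("list", n); any_sp <- FALSE
  for (t in seq_len(n)) {
    vinf <- params$EL + params$R * I[t, ]
    active <- refr <= 0L
    V[active] <- vinf[active] + (V[active] - vinf[active]) * decay
    refr[!active] <- refr[!active] - 1L
    fired <- active & (V >= params$V_th)
    if (any(fired)) {
      sp_step[[t]] <- which(fired)
      V[fired] <- params$V_reset
      refr[fired] <- ref_steps
      any_sp <- TRUE
    }
  }
  trains <- rep(list(numeric(0)), m)
  if (any_sp) {
    steps <- rep.int(seq_len(n), lengths(sp_step))
    ids <- unlist(sp_step, use.names = FALSE)
    times <- (steps - 1) * dt
    trains <- split(times, factor(ids, levels = seq_len(m)))
    trains <- lapply(trains, as.numeric)
  }
  spike_trains(trains, duration = n * dt, population = "m1")
}

#' Default TM synapse classes of the corticospinal pathway
#'
#' Named TM parameter sets for the three M1 input pathways: DBS-activated
#' axons (`dbs_m1_axon`), Vim spikes (`vim_m1`) and the tremor background
#' (`tremor_m1`). The exact fitted values of the source model are not
#' published; these defaults are uncalibrated placeholders (all depressing)
#' chosen once against the qualitative pathway behaviour (see vignette).
#'
#' @return Named list of [tm_params].
#' @export
m1_synapse_defaults <- function() {
  list(
    dbs_m1_axon = tm_params(U = 0.35, tau_fac = 0, tau_dep = 250,
                            tau_syn = 12, gain = 800, sign = 1),
    vim_m1 = tm_params(U = 0.25, tau_fac = 0, tau_dep = 120,
                       tau_syn = 10, gain = 100, sign = 1),
    tremor_m1 = tm_params(U = 0.30, tau_fac = 0, tau_dep = 200,
                          tau_syn = 15, gain = 360, sign = 1)
  )
}

#' Simulate the M1 population response to DBS, Vim firing and tremor drive
#'
#' Each of the `N_c` M1 neurons receives three TM-synaptic currents: the
#' shared DBS pulse train through the axonal synapse (DBS activates the axons
#' synapsing onto M1, so this current is common to the population), an
#' independent Poisson realization of the Vim firing rate, and an independent
#' Poisson realization of the tremor background rate. The summed current
#' drives the LIF membrane.
#'
#' @param dbs A [pulse_train].
#' @param vim_rate,tremor [rate_signal]s on a common grid.
#' @param m1 An [m1_params] object.
#' @param synapses Named list of [tm_params] with elements `dbs_m1_axon`,
#'   `vim_m1`, `tremor_m1` (default [m1_synapse_defaults()]).
#' @param seed Optional integer seed for the Poisson realizations.
#' @param I_const Test hook: if non-`NULL`, a constant current (nA) injected
#'   into every neuron in place of all synaptic input.
#' @return A [spike_trains] object (`N_c` neurons).
#' @export
simulate_m1 <- function(dbs, vim_rate, tremor, m1 = m1_params(),
                        synapses = m1_synapse_defaults(), seed = NULL,
                        I_const = NULL) {
  stopifnot(inherits(vim_rate, "rate_signal"), inherits(tremor, "rate_signal"))
  if (abs(vim_rate$dt - tremor$dt) > 1e-12 ||
      length(vim_rate$values) != length(tremor$values))
    stop("`vim_rate` and `tremor` must share the same time grid", call. = FALSE)
  dt <- vim_rate$dt
  n <- length(vim_rate$values)
  duration <- vim_rate$duration
  if (!is.null(I_const)) {
    I <- matrix(I_const, nrow = n, ncol = m1$N_c)
    return(lif_spikes(I, m1, dt = dt))
  }
  i_axon <- tm_current(dbs, synapses$dbs_m1_axon, dt = dt, duration = duration)
  p_vim <- vim_rate$values * dt / 1000
  p_tre <- tremor$values * dt / 1000
  if (any(p_vim > 0.3) || any(p_tre > 0.3))
    stop("rate * dt / 1000 exceeds 0.3; use a smaller dt", call. = FALSE)
  grid <- (seq_len(n) - 1) * dt
  with_seed(seed, {
    I <- matrix(0, nrow = n, ncol = m1$N_c)
    for (j in seq_len(m1$N_c)) {
      vim_tr <- grid[runif(n) < p_vim]
      tre_tr <- grid[runif(n) < p_tre]
      I[, j] <- i_axon +
        tm_current(vim_tr, synapses$vim_m1, dt = dt, duration = duration) +
        tm_current(tre_tr, synapses$tremor_m1, dt = dt, duration = duration)
    }
    lif_spikes(I, m1, dt = dt)
  })
}
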