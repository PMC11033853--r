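#' Vim firing-rate network parameters
#'
#' Three-population recurrent firing-rate network generating the instantaneous
#' Vim firing rate under DBS: the DBS-targeted Vim population, an external
#' excitatory population and an inhibitory population, coupled by signed
#' weights and driven through a depressing TM synapse by the DBS pulse train.
#' Each population obeys Wilson-Cowan-style dynamics
#' `tau * dr/dt = -r + F(W r + drive + I_dbs)` with a saturating
#' rectified-sigmoid activation `F(x) = max / (1 + exp(-(x - theta) / slope))`.
#'
#' The published fits of the upstream clinical Vim model are not available, so
#' the shipped weights, time constants and drives are uncalibrated placeholder
#' values chosen once to satisfy the qualitative targets stated for this
#' pathway: a DBS-OFF baseline near 25 Hz (clinically 10-40 Hz) and a large
#' onset transient followed by partial adaptation under high-frequency DBS.
#'
#' @param weights 3x3 coupling matrix (rows = targets, columns = sources, in
#'   order vim, excitatory, inhibitory). Inhibitory outgoing weights must be
#'   <= 0, vim/excitatory outgoing weights >= 0.
#' @param tau_rate Per-population rate time constants (ms, > 0).
#' @param act_max,act_theta,act_slope Per-population activation maximum (Hz),
#'   threshold and slope (input units).
#' @param baseline_drive Per-population tonic input.
#' @param dbs_synapse [tm_params] for the DBS-to-Vim pathway.
#' @param dbs_coupling Fraction of the DBS current received by each
#'   population (default: Vim only).
#' @return An object of class `vim_network_params`.
#' @export
vim_network_params <- function(
    weights = rbind(c(0.0, 0.4, -0.6),
                    c(0.6, 0.0, -0.3),
                    c(0.5, 0.4,  0.0)),
    tau_rate = c(5, 15, 15),
    act_max = c(250, 150, 150),
    act_theta = c(30, 30, 30),
    act_slope = c(12, 12, 12),
    baseline_drive = c(3.63, 4.37, -16.96),
    dbs_synapse = tm_params(U = 0.2, tau_fac = 0, tau_dep = 250,
                            tau_syn = 15, gain = 900, sign = 1),
    dbs_coupling = c(1, 0, 0)) {
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(3, 3))) stop("`weights` must be 3x3", call. = FALSE)
  if (any(weights[, 3] > 0))
    stop("inhibitory outgoing weights must be <= 0", call. = FALSE)
  if (any(weights[, 1:2] < 0))
    stop("vim/excitatory outgoing weights must be >= 0", call. = FALSE)
  if (any(tau_rate <= 0) || any(act_max <= 0) || any(act_slope <= 0))
    stop("time constants, activation maxima and slopes must be > 0",
         call. = FALSE)
  structure(list(weights = weights, tau_rate = tau_rate, act_max = act_max,
                 act_theta = act_theta, act_slope = act_slope,
                 baseline_drive = baseline_drive, dbs_synapse = dbs_synapse,
                 dbs_coupling = dbs_coupling),
            class = "vim_network_params")
}

rate_activation <- function(x, params) {
  params$act_max / (1 + exp(-(x - params$act_theta) / params$act_slope))
}

#' DBS-OFF fixed point of the rate network
#'
#' Solves `r* = F(W r* + drive)` by damped fixed-point iteration. The
#' simulated DBS-OFF steady state should match this analytic fixed point.
#'
#' @param params A [vim_network_params] object.
#' @param damping Step fraction per iteration (0, 1].
#' @param tol Convergence tolerance on the rate (Hz).
#' @param max_iter Iteration cap.
#' @return Numeric length-3 vector of fixed-point rates (Hz).
#' @export
vim_fixed_point <- function(params, damping = 0.2, tol = 1e-10,
                            max_iter = 10000) {
  r <- c(20, 20, 20)
  for (i in seq_len(max_iter)) {
    f <- rate_activation(drop(params$weights %*% r) + params$baseline_drive,
                         params)
    r_new <- (1 - damping) * r + damping * f
    if (max(abs(r_new - r)) < tol) return(r_new)
    r <- r_new
  }
  warning("fixed-point iteration did not converge")
  r
}

#' Simulate the Vim firing rate under DBS
#'
#' Integrates the three-population rate network driven by the TM post-synaptic
#' current of the DBS pulse train, with exponential-Euler stepping, and
#' returns the Vim population trace. The simulation is deterministic.
#'
#' @param dbs A [pulse_train] (empty train = DBS-OFF).
#' @param params A [vim_network_params] object.
#' @param duration Simulation span (ms).
#' @param dt Integration step (ms; default 0.1, which resolves the 1-ms
#'   refractory scale used downstream).
#' @param full If `TRUE`, attach all three population traces as attribute
#'   `"populations"`.
#' @return A [rate_signal] with the Vim rate (Hz).
#' @export
simulate_vim_rate <- function(dbs, params, duration, dt = 0.1, full = FALSE) {
  stopifnot(inherits(dbs, "pulse_train"))
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(dt, "dt")
  i_dbs <- tm_current(dbs, params$dbs_synapse, dt = dt, duration = duration)
  n <- length(i_dbs)
  W <- params$weights; drv <- params$baseline_drive
  cpl <- params$dbs_coupling
  decay <- exp(-dt / params$tau_rate)
  r <- vim_fixed_point(params)          # start at the DBS-OFF operating point
  out <- matrix(0, nrow = n, ncol = if (full) 3 else 1)
  w11 <- W[1,1]; w12 <- W[1,2]; w13 <- W[1,3]
  w21 <- W[2,1]; w22 <- W[2,2]; w23 <- W[2,3]
  w31 <- W[3,1]; w32 <- W[3,2]; w33 <- W[3,3]
  r1 <- r[1]; r2 <- r[2]; r3 <- r[3]
  m1 <- params$act_max[1]; m2 <- params$act_max[2]; m3 <- params$act_max[3]
  th1 <- params$act_theta[1]; th2 <- params$act_theta[2]; th3 <- params$act_theta[3]
  s1 <- params$act_slope[1]; s2 <- params$act_slope[2]; s3 <- params$act_slope[3]
  d1 <- decay[1]; d2 <- decay[2]; d3 <- decay[3]
  c1 <- cpl[1]; c2 <- cpl[2]; c3 <- cpl[3]
  b1 <- drv[1]; b2 <- drv[2]; b3 <- drv[3]
  for (t in seq_len(n)) {
    i_t <- i_dbs[t]
    f1 <- m1 / (1 + exp(-((w11*r1 + w12*r2 + w13*r3 + b1 + c1*i_t) - th1) / s1))
    f2 <- m2 / (1 + exp(-((w21*r1 + w22*r2 + w23*r3 + b2 + c2*i_t) - th2) / s2))
    f3 <- m3 / (1 + exp(-((w31*r1 + w32*r2 + w33*r3 + b3 + c3*i_t) - th3) / s3))
    r1 <- f1 + (r1 - f1) * d1
    r2 <- f2 + (r2 - f2) * d2
    r3 <- f3 + (r3 - f3) * d3
    out[t, 1] <- r1
    if (full) { out[t, 2] <- r2; out[t, 3] <- r3 }
  }
  if (mean(out[, 1] >= 0.999 * m1) > 0.5)
    warning("Vim rate saturated at the activation maximum for >50% of samples")
  sig <- rate_signal(out[, 1], dt = dt)
  if (full) attr(sig, "populations") <- out
  sig
}

#' Vim rate response to a given DBS frequency
#'
#' Convenience composition of [pulse_train()] and [simulate_vim_rate()], the
#' encoding half of the closed-loop plant. The biomarker downstream is
#' validated on stimulation frequencies in `[0, 200]` Hz only, so larger
#' frequencies are rejected.
#'
#' @param frequency DBS frequency in Hz, in `[0, 200]` (0 = DBS-OFF).
#' @inheritParams simulate_vim_rate
#' @return A [rate_signal].
#' @export
vim_rate_for_frequency <- function(frequency, params, duration, dt = 0.1) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency < 0 ||
      frequency > 200)
    stop("`frequency` must lie in the validated range [0, 200] Hz",
         call. = FALSE)
  simulate_vim_rate(pulse_train(frequency, duration), params,
                    duration = duration, dt = dt)
}
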