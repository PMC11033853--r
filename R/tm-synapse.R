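#' Tsodyks-Markram synapse parameters
#'
#' Short-term synaptic plasticity is the central DBS mechanism in this model:
#' every pathway (DBS pulses into Vim, DBS-activated axons into M1, Vim spikes
#' into M1, tremor background into M1) passes through a Tsodyks-Markram (TM)
#' synapse whose per-event release is shaped by resource depression and,
#' optionally, facilitation. Each presynaptic event releases a fraction
#' `u * r` of resources and the post-synaptic current (PSC) jumps by
#' `sign * gain * u * r`, decaying exponentially with `tau_syn` in between.
#'
#' The shipped per-pathway defaults are uncalibrated placeholders: the source
#' clinical fits are not published, so values were chosen once to satisfy the
#' qualitative behaviour of the pathway (see the package vignette). All
#' defaults are depressing (`tau_fac = 0`), the regime that underlies
#' high-frequency DBS suppression.
#'
#' @param U Baseline release probability, in (0, 1].
#' @param tau_fac Facilitation time constant (ms); 0 disables facilitation.
#' @param tau_dep Depression recovery time constant (ms, > 0).
#' @param tau_syn PSC decay time constant (ms, > 0).
#' @param gain Absolute synaptic efficacy: PSC jump scale (nA).
#' @param sign +1 excitatory, -1 inhibitory.
#' @return An object of class `tm_params`.
#' @seealso [tm_current()]
#' @export
tm_params <- function(U = 0.2, tau_fac = 0, tau_dep = 100, tau_syn = 10,
                      gain = 1, sign = 1) {
  if (!(U > 0 && U <= 1)) stop("`U` must be in (0, 1]", call. = FALSE)
  stop_if_not_scalar_pos(tau_fac, "tau_fac", allow_zero = TRUE)
  stop_if_not_scalar_pos(tau_dep, "tau_dep")
  stop_if_not_scalar_pos(tau_syn, "tau_syn")
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1", call. = FALSE)
  structure(list(U = U, tau_fac = tau_fac, tau_dep = tau_dep,
                 tau_syn = tau_syn, gain = gain, sign = sign),
            class = "tm_params")
}

# Event-driven TM state iteration: exact exponential updates between events.
# Canonical ordering at each event: relax, facilitate u, release u*r, deplete r.
# With tau_fac = 0 the release variable is always exactly U, so the first
# event from rest releases gain * U.
tm_event_states <- function(event_times, params) {
  K <- length(event_times)
  u <- numeric(K); r <- numeric(K); jump <- numeric(K)
  u_prev <- 0; r_prev <- 1; t_prev <- -Inf
  for (k in seq_len(K)) {
    dtk <- event_times[k] - t_prev
    u_rel <- if (params$tau_fac > 0) u_prev * exp(-dtk / params$tau_fac) else 0
    r_rec <- 1 + (r_prev - 1) * exp(-dtk / params$tau_dep)
    u_plus <- u_rel + params$U * (1 - u_rel)
    jump[k] <- params$gain * params$sign * u_plus * r_rec
    u[k] <- u_plus
    r[k] <- r_rec - u_plus * r_rec
    u_prev <- u_plus; r_prev <- r[k]; t_prev <- event_times[k]
  }
  list(u_rel = u, r_avail = r, jump = jump,
       r_before = if (K) jump / (params$gain * params$sign * u) else numeric(0))
}

#' TM post-synaptic current from a pulse or spike train
#'
#' Drives a Tsodyks-Markram synapse with presynaptic events (DBS pulses are
#' treated as presynaptic events of unit weight) and returns the resulting PSC
#' sampled on a regular grid. State updates between events use exact
#' exponential relaxation, so per-event amplitudes are independent of `dt`.
#'
#' @param train A [pulse_train] or a numeric vector of event times (ms).
#' @param params A [tm_params] object.
#' @param dt Sample interval (ms, > 0).
#' @param duration Trace span (ms); samples at `0, dt, ..., duration - dt`.
#' @return Numeric vector of PSC values (nA), length `duration / dt`.
#' @examples
#' p <- tm_params(U = 0.2, tau_dep = 100, tau_syn = 10, gain = 1)
#' i <- tm_current(pulse_train(130, 500), p, dt = 0.1, duration = 500)
#' @export
tm_current <- function(train, params, dt = 0.1, duration) {
  stop_if_not_scalar_pos(dt, "dt")
  stop_if_not_scalar_pos(duration, "duration")
  times <- if (inherits(train, "pulse_train")) train$times else as.numeric(train)
  if (any(times < 0) || any(times >= duration))
    stop("event times must lie within [0, duration)", call. = FALSE)
  n <- round(duration / dt)
  out <- numeric(n)
  if (!length(times)) return(out)
  st <- tm_event_states(times, params)
  # Deposit each jump at the first grid point >= event, pre-decayed to that
  # grid time, then propagate with a first-order recursive filter (exact for
  # a superposition of exponentials sampled on a regular grid).
  idx <- as.integer(ceiling(times / dt - 1e-9)) + 1L
  keep <- idx <= n
  tgrid <- (idx - 1) * dt
  dep <- st$jump * exp(-(tgrid - times) / params$tau_syn)
  x <- numeric(n)
  for (k in which(keep)) x[idx[k]] <- x[idx[k]] + dep[k]
  as.numeric(stats::filter(x, exp(-dt / params$tau_syn), method = "recursive"))
}

#' Pool TM currents over several presynaptic trains
#'
#' Each train drives its own independent synapse (per-synapse state), and the
#' resulting PSCs add linearly.
#'
#' @param trains List of [pulse_train] objects or numeric event-time vectors.
#' @param params A single [tm_params] applied to every train, or a list with
#'   one [tm_params] per train.
#' @inheritParams tm_current
#' @return Numeric vector: the summed current trace (zero trace for an empty
#'   list).
#' @export
pool_tm_currents <- function(trains, params, dt = 0.1, duration) {
  n <- round(duration / dt)
  out <- numeric(n)
  if (!length(trains)) return(out)
  per_train <- !inherits(params, "tm_params")
  if (per_train && length(params) != length(trains))
    stop("`params` must be one tm_params or one per train", call. = FALSE)
  for (k in seq_along(trains)) {
    pk <- if (per_train) params[[k]] else params
    out <- out + tm_current(trains[[k]], pk, dt = dt, duration = duration)
  }
  out
}
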