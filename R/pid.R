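#' PID controller gains and schedule
#'
#' Position-form discrete PID acting on the error between the system output
#' `z(u)` and the control target: the next DBS frequency is
#' `u = Kp e_m + Ki sum_j e_j dt + Kd (e_m - e_{m-1}) / dt`, clamped to the
#' valid stimulation range. The defaults are the study's published gains and
#' schedule (20-s control step, 10-min horizon).
#'
#' @param Kp Proportional gain (Hz per mV^2).
#' @param Ki Integral gain (Hz per mV^2 min).
#' @param Kd Derivative gain (Hz min per mV^2).
#' @param dt_ctrl Control step (min).
#' @param t_end Control horizon (min).
#' @param u_min,u_max Frequency clamp (Hz).
#' @param u_init Initial DBS frequency (Hz); the lowest valid frequency by
#'   default.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(Kp = 1e3, Ki = 1e5, Kd = 5e3, dt_ctrl = 1 / 3,
                      t_end = 10, u_min = 10, u_max = 200, u_init = 10) {
  stopifnot(dt_ctrl > 0, u_min < u_max)
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd, dt_ctrl = dt_ctrl, t_end = t_end,
                 u_min = u_min, u_max = u_max, u_init = u_init),
            class = "pid_gains")
}

#' One position-form PID update
#'
#' Computes the next frequency from the full error history (the integral term
#' is the running sum of all errors times the control step; the derivative
#' term is zero at the first step), then clamps to `[u_min, u_max]`.
#'
#' @param error_history Numeric vector `e(t_1) .. e(t_m)` (most recent last).
#' @param gains A [pid_gains] object.
#' @return The clamped next frequency (Hz), with the raw (unclamped) value as
#'   attribute `"raw"`.
#' @export
pid_step <- function(error_history, gains = pid_gains()) {
  if (!length(error_history) || any(!is.finite(error_history)))
    stop("error history must be non-empty and finite", call. = FALSE)
  m <- length(error_history)
  e_m <- error_history[m]
  deriv <- if (m == 1) 0 else (e_m - error_history[m - 1]) / gains$dt_ctrl
  raw <- gains$Kp * e_m + gains$Ki * sum(error_history) * gains$dt_ctrl +
    gains$Kd * deriv
  structure(min(gains$u_max, max(gains$u_min, raw)), raw = raw)
}

#' Build the biomarker plant u -> z(u)
#'
#' The plant evaluated by the closed loop: simulate the Vim rate at frequency
#' `u`, estimate the EMG with the fitted polynomial biomarker (fresh noise on
#' every call unless a seed is pinned), and reduce it to the scalar system
#' output.
#'
#' @param est A fitted [fit_biomarker()] object.
#' @param vim_params A [vim_network_params] object.
#' @param spectral A [spectral_params] object.
#' @param dt Simulation step for the rate network (ms).
#' @return A function `plant(u, seed = NULL)` returning `z(u)` (numeric).
#'   `u` outside `[10, 200]` Hz is an error (the biomarker's validated
#'   range).
#' @export
make_model_plant <- function(est, vim_params = vim_network_params(),
                             spectral = spectral_params(), dt = 0.1) {
  force(est); force(vim_params); force(spectral); force(dt)
  duration <- spectral$T_eval * 1000
  function(u, seed = NULL) {
    if (u < 10 || u > 200)
      stop("plant is defined on the validated DBS range [10, 200] Hz",
           call. = FALSE)
    x <- vim_rate_for_frequency(u, vim_params, duration = duration, dt = dt)
    yhat <- predict(est, x, add_noise = TRUE, seed = seed)
    system_output(yhat, u = u, params = spectral)$z
  }
}

#' Control target from a reference DBS frequency
#'
#' Defines the target `beta_z` as the biomarker power generated at a fixed
#' reference stimulation frequency, together with the empirical noise scale
#' of the plant there (used for the convergence band).
#'
#' @param frequency Reference DBS frequency (Hz).
#' @param plant A plant function from [make_model_plant()].
#' @param n_rep Number of plant replicates for the mean and sd.
#' @param seed Optional integer seed.
#' @return List with `beta_z` (mean z), `noise_sd` (sd over replicates) and
#'   `frequency`.
#' @export
control_target <- function(frequency, plant, n_rep = 10, seed = NULL) {
  zs <- with_seed(seed, replicate(n_rep, plant(frequency)))
  list(beta_z = mean(zs), noise_sd = stats::sd(zs), frequency = frequency)
}

#' Run the closed loop
#'
#' Iterates the PID-controlled plant from `u_init` on the control schedule,
#' recording `(t_m, u_m, z_m, e_m)` at every step. The integral term is
#' frozen while the output clamp is active and the error drives it further
#' out of range (anti-windup; without it the large integral gain would wind
#' up irrecoverably against the clamp). Convergence is declared when `|e|`
#' stays within the noise band for the final three steps; the settling time
#' is the first time the error has remained in the band for three
#' consecutive steps.
#'
#' @param target A list from [control_target()] (preferred; supplies the
#'   noise band) or a bare numeric `beta_z`.
#' @param plant Function `u -> z` (see [make_model_plant()]).
#' @param gains A [pid_gains] object.
#' @param noise_band Half-width of the convergence band on `|e|`. Defaults to
#'   `2 * target$noise_sd` when the target carries a noise scale; required
#'   otherwise.
#' @param seed Optional integer seed for the whole run (plant noise).
#' @return An object of class `control_trace`: data frame with columns
#'   `t_min`, `u_hz`, `z`, `e` and attributes `beta_z`, `converged`,
#'   `settling_time` (min, `NA` if never settled), `noise_band`.
#' @export
run_closed_loop <- function(target, plant, gains = pid_gains(),
                            noise_band = NULL, seed = NULL) {
  beta_z <- if (is.list(target)) target$beta_z else target
  stopifnot(is.finite(beta_z), beta_z >= 0)
  if (is.null(noise_band)) {
    if (is.list(target) && !is.null(target$noise_sd))
      noise_band <- 2 * target$noise_sd
    else stop("`noise_band` is required when the target has no noise scale",
              call. = FALSE)
  }
  M <- as.integer(round(gains$t_end / gains$dt_ctrl)) + 1L
  t_min <- (seq_len(M) - 1) * gains$dt_ctrl
  u <- numeric(M); z <- numeric(M); e <- numeric(M)
  with_seed(seed, {
    u_cur <- gains$u_init
    integ <- 0
    for (m in seq_len(M)) {
      u[m] <- u_cur
      z[m] <- plant(u_cur)
      if (!is.finite(z[m])) stop("plant returned a non-finite output",
                                 call. = FALSE)
      e[m] <- z[m] - beta_z
      integ_new <- integ + e[m] * gains$dt_ctrl
      deriv <- if (m == 1) 0 else (e[m] - e[m - 1]) / gains$dt_ctrl
      raw <- gains$Kp * e[m] + gains$Ki * integ_new + gains$Kd * deriv
      u_next <- min(gains$u_max, max(gains$u_min, raw))
      if (abs(raw - u_next) > 0 && sign(e[m]) == sign(raw - u_next))
        integ_new <- integ                     # anti-windup: freeze integral
      integ <- integ_new
      u_cur <- u_next
    }
  })
  in_band <- abs(e) <= noise_band
  # settled once the error has stayed in the band for 3 consecutive steps
  run3 <- in_band & c(FALSE, FALSE, head(in_band, -2)) &
    c(FALSE, head(in_band, -1))
  out <- data.frame(t_min = t_min, u_hz = u, z = z, e = e)
  attr(out, "beta_z") <- beta_z
  attr(out, "noise_band") <- noise_band
  attr(out, "converged") <- all(in_band[(M - 2):M])
  attr(out, "settling_time") <- if (any(run3)) t_min[which(run3)[1]] else NA_real_
  class(out) <- c("control_trace", "data.frame")
  out
}

#' @export
print.control_trace <- function(x, ...) {
  cat(sprintf("closed-loop control trace: %d steps, target beta_z = %.4g\n",
              nrow(x), attr(x, "beta_z")))
  cat(sprintf("  converged: %s; settling time: %s min; final u = %.1f Hz\n",
              attr(x, "converged"),
              format(attr(x, "settling_time")), x$u_hz[nrow(x)]))
  invisible(x)
}

#' @export
plot.control_trace <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$t_min, x$u_hz, type = "s", xlab = "time (min)",
       ylab = "DBS frequency (Hz)", ...)
  plot(x$t_min, x$z, type = "b", xlab = "time (min)", ylab = "system output z")
  abline(h = attr(x, "beta_z"), lty = 2)
  abline(h = attr(x, "beta_z") + c(-1, 1) * attr(x, "noise_band"),
         lty = 3, col = "grey50")
  invisible(x)
}

#' Closed-loop runs over several control targets
#'
#' Independent closed-loop runs, one per target. With a plant that decreases
#' in frequency, the steady-state frequencies are ordered inversely to the
#' target powers (a higher power target is reached at a lower frequency).
#'
#' @param targets List of targets ([control_target()] lists or numbers).
#' @param plant,gains,noise_band,seed As in [run_closed_loop()].
#' @return List of `control_trace` objects.
#' @export
multi_target_sweep <- function(targets, plant, gains = pid_gains(),
                               noise_band = NULL, seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", length(targets))
           else as.list(seed + seq_along(targets) - 1)
  Map(function(tg, s) run_closed_loop(tg, plant, gains = gains,
                                      noise_band = noise_band, seed = s),
      targets, seeds)
}
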