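#' Surface EMG signal container
#'
#' @param values EMG samples (mV).
#' @param fs Sampling rate (Hz).
#' @param kind `"reference"` (full biophysical simulation) or `"estimated"`
#'   (polynomial biomarker).
#' @return An object of class `emg_signal`.
#' @export
emg_signal <- function(values, fs, kind = c("reference", "estimated")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("EMG values must be finite", call. = FALSE)
  structure(list(values = values, fs = fs,
                 duration = 1000 * length(values) / fs, kind = kind),
            class = "emg_signal")
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("%s EMG: %d samples at %g Hz (%.6g ms), sd %.4f mV\n",
              x$kind, length(x$values), x$fs, x$duration, sd(x$values)))
  invisible(x)
}

#' @export
as.data.frame.emg_signal <- function(x, ...) {
  data.frame(time_ms = (seq_along(x$values) - 1) * 1000 / x$fs,
             emg_mV = x$values)
}

#' @export
plot.emg_signal <- function(x, ...) {
  d <- as.data.frame(x)
  plot(d$time_ms, d$emg_mV, type = "l", xlab = "time (ms)",
       ylab = "EMG (mV)", ...)
}

#' Motor-unit action potential parameters
#'
#' Each motoneuron spike elicits a stereotyped motor-unit action potential
#' (MUAP) in its muscle fibres after the motoneuron-to-muscle conduction
#' delay. The waveform is the first-order Hermite-Rodriguez form
#' `A * (t - tau) * exp(-((t - tau) / lambda)^2)`; a literal reading of the
#' published exponent, `exp(-(t - tau) / lambda^2)`, is available behind
#' `hermite = FALSE`.
#'
#' @param lambda Time factor of the MUAP (ms).
#' @param td_mm Motoneuron-to-muscle conduction delay (ms).
#' @param mu Mean of the exponential amplitude distribution (mV per ms of the
#'   waveform argument, so the summed EMG lands on the mV scale).
#' @param noise_sd Standard deviation of the additive Gaussian white noise of
#'   the reference EMG (mV).
#' @param fs_emg EMG sampling rate (Hz).
#' @param hermite Use the Hermite-Rodriguez exponent (default) or the literal
#'   alternative.
#' @return An object of class `muap_params`.
#' @export
muap_params <- function(lambda = 2, td_mm = 10, mu = 7e-3, noise_sd = 0.025,
                        fs_emg = 500, hermite = TRUE) {
  stop_if_not_scalar_pos(lambda, "lambda")
  stop_if_not_scalar_pos(mu, "mu")
  stop_if_not_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  structure(list(lambda = lambda, td_mm = td_mm, mu = mu,
                 noise_sd = noise_sd, fs_emg = fs_emg, hermite = hermite),
            class = "muap_params")
}

#' Draw motor-unit amplitude scale factors
#'
#' Amplitudes are i.i.d. exponential with mean `mu`, drawn once per run: one
#' motor unit keeps one amplitude across all of its spikes.
#'
#' @param n Number of motor units.
#' @param mu Mean amplitude.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` amplitudes.
#' @export
draw_muap_amplitudes <- function(n, mu = 7e-3, seed = NULL) {
  stopifnot(n >= 1, mu > 0)
  with_seed(seed, rexp(n, rate = 1 / mu))
}

#' Single MUAP waveform
#'
#' @param spike_time Motoneuron spike time (ms); the waveform onset is
#'   `spike_time + td_mm`.
#' @param Aj Amplitude scale factor (>= 0).
#' @param params A [muap_params] object.
#' @param dt Sample interval (ms).
#' @param duration Span of the returned trace (ms).
#' @return Numeric vector sampled at `dt`: zero before onset, then the MUAP.
#' @export
muap_waveform <- function(spike_time, Aj, params = muap_params(), dt = 0.1,
                          duration) {
  stopifnot(Aj >= 0)
  t <- seq(0, duration - dt / 2, by = dt)
  arg <- t - (spike_time + params$td_mm)
  env <- if (params$hermite) exp(-(arg / params$lambda)^2)
         else exp(-arg / params$lambda^2)
  ifelse(arg >= 0, Aj * arg * env, 0)
}

#' Synthesize the reference surface EMG from motoneuron spikes
#'
#' The surface EMG is the linear summation of the MUAPs of all motor units
#' over all of their spikes, plus low-level Gaussian white noise. The MUAP
#' superposition is computed on the fine simulation grid and band-limited by
#' averaging into `fs_emg` bins (box anti-aliasing of the sharp MUAP onsets),
#' and the white noise is added at the EMG sampling rate.
#'
#' @param motoneuron_spikes A [spike_trains] object.
#' @param params A [muap_params] object.
#' @param seed Optional integer seed (amplitude draws, then noise).
#' @param dt Fine simulation step used for the MUAP superposition (ms).
#' @param amplitudes Optional fixed amplitude vector (bypasses the draw).
#' @return An [emg_signal] of kind `"reference"` with attribute
#'   `"amplitudes"`.
#' @export
synthesize_emg <- function(motoneuron_spikes, params = muap_params(),
                           seed = NULL, dt = 0.1, amplitudes = NULL) {
  stopifnot(inherits(motoneuron_spikes, "spike_trains"))
  n_units <- length(motoneuron_spikes$trains)
  duration <- motoneuron_spikes$duration
  n_fine <- round(duration / dt)
  factor <- round(1000 / (params$fs_emg * dt))
  if (abs(factor * dt * params$fs_emg - 1000) > 1e-6)
    stop("fs_emg must be commensurate with dt", call. = FALSE)
  with_seed(seed, {
    A <- if (is.null(amplitudes)) rexp(n_units, rate = 1 / params$mu)
         else amplitudes
    # kernel sampled on the fine grid; support to 6*lambda covers the
    # Hermite-Rodriguez tail below 1e-14 of the peak
    k_len <- ceiling(6 * params$lambda / dt) + 1L
    k_t <- (seq_len(k_len) - 1) * dt
    kern <- if (params$hermite) k_t * exp(-(k_t / params$lambda)^2)
            else k_t * exp(-k_t / params$lambda^2)
    y <- numeric(n_fine + k_len)
    for (j in seq_len(n_units)) {
      tr <- motoneuron_spikes$trains[[j]]
      if (!length(tr)) next
      onset_idx <- as.integer(round((tr + params$td_mm) / dt)) + 1L
      onset_idx <- onset_idx[onset_idx <= n_fine]
      for (i0 in onset_idx)
        y[i0:(i0 + k_len - 1L)] <- y[i0:(i0 + k_len - 1L)] + A[j] * kern
    }
    y <- y[seq_len(n_fine)]
    y_emg <- bin_average(y, factor)
    y_emg <- y_emg + rnorm(length(y_emg), 0, params$noise_sd)
    out <- emg_signal(y_emg, fs = params$fs_emg, kind = "reference")
    attr(out, "amplitudes") <- A
    out
  })
}
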