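#' Tremor background waveform parameters
#'
#' Essential-tremor EMG shows burst activity in the 4-8 Hz band. The tremor
#' drive into the motor cortex is modelled as a periodic firing-rate waveform
#' of bursts at `burst_rate`; each burst consists of `waves_per_burst`
#' consecutive sinusoidal waves of period `wave_period` riding on a baseline,
#' and the waveform is rectified at zero. With a large amplitude-to-baseline
#' ratio the rectification lifts the mean rate during a burst, which is what
#' puts the dominant spectral component at the burst rate rather than at the
#' intra-burst wave frequency.
#'
#' @param burst_rate Burst repetition rate (Hz, default 6).
#' @param waves_per_burst Sinusoid cycles per burst (default 3).
#' @param wave_period Period of each wave (ms, default 20).
#' @param baseline Baseline firing rate (Hz).
#' @param amplitude Sinusoid peak amplitude (Hz).
#' @return An object of class `tremor_params`.
#' @export
tremor_params <- function(burst_rate = 6, waves_per_burst = 3,
                          wave_period = 20, baseline = 4, amplitude = 70) {
  if (any(c(burst_rate, waves_per_burst, wave_period, baseline, amplitude) < 0))
    stop("tremor parameters must be nonnegative", call. = FALSE)
  if (waves_per_burst * wave_period > 1000 / burst_rate)
    stop("burst (waves_per_burst * wave_period) must fit within one burst period",
         call. = FALSE)
  structure(list(burst_rate = burst_rate, waves_per_burst = waves_per_burst,
                 wave_period = wave_period, baseline = baseline,
                 amplitude = amplitude),
            class = "tremor_params")
}

#' Tremor-inducing background firing rate
#'
#' Generates the periodic burst waveform: each period of `1000 / burst_rate`
#' ms starts with `waves_per_burst` full sinusoid cycles on top of the
#' baseline, followed by flat baseline; negative values are rectified to zero.
#'
#' @param params A [tremor_params] object.
#' @param duration Span (ms).
#' @param dt Sample interval (ms).
#' @return A [rate_signal] (Hz).
#' @export
tremor_rate <- function(params, duration, dt = 0.1) {
  stopifnot(inherits(params, "tremor_params"))
  t <- seq(0, duration - dt / 2, by = dt)
  period <- 1000 / params$burst_rate
  tp <- t %% period
  burst_len <- params$waves_per_burst * params$wave_period
  v <- rep(params$baseline, length(t))
  in_burst <- tp < burst_len
  v[in_burst] <- params$baseline +
    params$amplitude * sin(2 * pi * tp[in_burst] / params$wave_period)
  rate_signal(pmax(0, v), dt = dt)
}
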