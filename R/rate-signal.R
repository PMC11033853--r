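#' Uniformly sampled firing-rate signal
#'
#' Container for nonnegative firing-rate traces (Hz): the simulated Vim rate
#' `x(t)` and the tremor background waveform both use it.
#'
#' @param values Rate samples (Hz, >= 0).
#' @param dt Sample interval (ms).
#' @return An object of class `rate_signal` with elements `values`, `dt` and
#'   `duration` (ms).
#' @export
rate_signal <- function(values, dt) {
  stop_if_not_scalar_pos(dt, "dt")
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("rate values must be finite and nonnegative", call. = FALSE)
  structure(list(values = values, dt = dt, duration = length(values) * dt),
            class = "rate_signal")
}

#' @export
print.rate_signal <- function(x, ...) {
  cat(sprintf("rate signal: %d samples at dt = %g ms (%.6g ms), mean %.2f Hz\n",
              length(x$values), x$dt, x$duration, mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.rate_signal <- function(x, ...) {
  data.frame(time_ms = (seq_along(x$values) - 1) * x$dt, rate_hz = x$values)
}

#' @export
plot.rate_signal <- function(x, ...) {
  d <- as.data.frame(x)
  plot(d$time_ms, d$rate_hz, type = "l", xlab = "time (ms)",
       ylab = "firing rate (Hz)", ...)
}

# Average consecutive blocks of `factor` samples (anti-aliased downsampling
# onto a coarser grid; used to move 0.1-ms simulation traces to the EMG rate).
bin_average <- function(values, factor) {
  n <- (length(values) %/% factor) * factor
  colMeans(matrix(values[seq_len(n)], nrow = factor))
}

# Resample a rate_signal to sampling rate fs (Hz) by bin averaging.
resample_rate <- function(x, fs) {
  factor <- round(1000 / (fs * x$dt))
  if (abs(factor * x$dt * fs - 1000) > 1e-6)
    stop("fs must be commensurate with the simulation step", call. = FALSE)
  rate_signal(bin_average(x$values, factor), dt = 1000 / fs)
}
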