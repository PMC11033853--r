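#' Population spike trains
#'
#' Per-neuron ordered spike times for the simulated populations (M1 cortical
#' neurons, spinal motoneurons).
#'
#' @param trains List with one numeric vector of spike times (ms, strictly
#'   increasing) per neuron.
#' @param duration Span covered by the recording/simulation (ms).
#' @param population Label, e.g. `"m1"` or `"motoneuron"`.
#' @return An object of class `spike_trains`.
#' @export
spike_trains <- function(trains, duration, population = "neurons") {
  stopifnot(is.list(trains))
  for (tr in trains)
    if (length(tr) && (any(diff(tr) <= 0) || any(tr < 0) || any(tr > duration)))
      stop("spike times must be strictly increasing within [0, duration]",
           call. = FALSE)
  structure(list(trains = trains, duration = duration,
                 population = population),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  n_sp <- sum(lengths(x$trains))
  cat(sprintf("%s spike trains: %d neurons, %d spikes, %.6g ms (mean %.2f Hz)\n",
              x$population, length(x$trains), n_sp, x$duration,
              1000 * n_sp / max(1, length(x$trains)) / x$duration))
  invisible(x)
}

#' @export
as.data.frame.spike_trains <- function(x, ...) {
  data.frame(
    neuron_id = rep.int(seq_along(x$trains), lengths(x$trains)),
    time_ms = unlist(x$trains, use.names = FALSE)
  )
}

#' Firing rates of a spike-train population
#'
#' @param x A [spike_trains] object.
#' @return Numeric vector of per-neuron mean rates (Hz).
#' @export
firing_rates <- function(x) {
  stopifnot(inherits(x, "spike_trains"))
  1000 * lengths(x$trains) / x$duration
}

#' @export
plot.spike_trains <- function(x, ...) {
  d <- as.data.frame(x)
  plot(d$time_ms, d$neuron_id, pch = ".", xlab = "time (ms)",
       ylab = "neuron", ...)
}
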