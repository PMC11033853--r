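#' DBS pulse trains
#'
#' A pulse train is the stimulation input of the model: an ordered set of DBS
#' pulse onset times at a nominal frequency. A frequency of 0 encodes the
#' DBS-OFF condition (empty train).
#'
#' @param frequency Stimulation frequency in Hz (>= 0; 0 gives an empty train).
#' @param duration Total span of the train in ms (> 0). Pulses lie in
#'   `[0, duration)`.
#' @param offset Time of the first pulse in ms (default 0).
#' @return An object of class `pulse_train`: a list with elements `times`
#'   (ms, strictly increasing), `frequency` (Hz) and `duration` (ms).
#' @examples
#' pulse_train(130, 1000)    # 130 pulses, spacing ~7.692 ms
#' pulse_train(0, 5000)      # DBS-OFF
#' @export
pulse_train <- function(frequency, duration, offset = 0) {
  stop_if_not_scalar_pos(frequency, "frequency", allow_zero = TRUE)
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(offset, "offset", allow_zero = TRUE)
  times <- if (frequency == 0) numeric(0) else {
    period <- 1000 / frequency
    n <- ceiling((duration - offset) / period - 1e-9)  # pulses in [offset, duration)
    offset + (seq_len(n) - 1) * period
  }
  structure(list(times = times, frequency = frequency, duration = duration),
            class = "pulse_train")
}

#' Construct a pulse train from explicit event times
#'
#' Wraps user-supplied (or recorded) pulse/spike onset times in the container
#' used throughout the package, validating ordering.
#'
#' @param times Numeric vector of onset times in ms, strictly increasing,
#'   within `[0, duration)`.
#' @param duration Span in ms.
#' @param frequency Optional nominal rate (Hz); defaults to the empirical rate.
#' @return A `pulse_train`.
#' @export
as_pulse_train <- function(times, duration, frequency = NULL) {
  times <- as.numeric(times)
  if (length(times) && (any(diff(times) <= 0) || any(times < 0) ||
                        any(times >= duration)))
    stop("`times` must be strictly increasing within [0, duration)",
         call. = FALSE)
  if (is.null(frequency)) frequency <- 1000 * length(times) / duration
  structure(list(times = times, frequency = frequency, duration = duration),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("DBS pulse train: %d pulses, %.6g Hz nominal, %.6g ms span\n",
              length(x$times), x$frequency, x$duration))
  invisible(x)
}

#' @export
length.pulse_train <- function(x) length(x$times)
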