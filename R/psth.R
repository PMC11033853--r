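#' Peristimulus time histogram parameters
#'
#' @param window Post-pulse lag interval (ms). The default upper bound,
#'   7.7 ms, is the 130-Hz inter-pulse interval; [compute_psth()] shortens it
#'   to the actual inter-pulse interval for faster trains.
#' @param kernel_sd Gaussian smoothing kernel sd (ms).
#' @param bin Histogram bin width (ms).
#' @return An object of class `psth_params`.
#' @export
psth_params <- function(window = c(0, 7.7), kernel_sd = 0.2, bin = 0.05) {
  stopifnot(kernel_sd > 0, diff(window) > 0, bin > 0)
  structure(list(window = window, kernel_sd = kernel_sd, bin = bin),
            class = "psth_params")
}

#' Pulse-aligned smoothed spike-rate histogram
#'
#' Collects spike lags within the post-pulse window after each DBS pulse,
#' histograms them, convolves with a Gaussian kernel (truncated at four
#' standard deviations and renormalized), and normalizes by the number of
#' pulses and the bin width, giving a pulse-locked instantaneous firing rate
#' in spikes/s. The integral of the curve over the window recovers the mean
#' number of in-window spikes per pulse (up to kernel truncation at the
#' edges).
#'
#' @param spikes A [spike_trains] object or a numeric vector of spike times
#'   (ms), e.g. read from an external single-unit recording.
#' @param pulses A [pulse_train] (must be non-empty).
#' @param params A [psth_params] object.
#' @return An object of class `psth`: list with `lag` (ms), `rate`
#'   (spikes/s per pulse), `per_pulse` (spikes/pulse per bin), `n_pulses`,
#'   `n_spikes`.
#' @export
compute_psth <- function(spikes, pulses, params = psth_params()) {
  stopifnot(inherits(pulses, "pulse_train"))
  if (!length(pulses$times)) stop("pulse train is empty", call. = FALSE)
  times <- if (inherits(spikes, "spike_trains"))
    sort(unlist(spikes$trains, use.names = FALSE)) else sort(as.numeric(spikes))
  w_hi <- params$window[2]
  if (length(pulses$times) > 1)
    w_hi <- min(w_hi, min(diff(pulses$times)))
  edges <- seq(params$window[1], w_hi, by = params$bin)
  if (edges[length(edges)] < w_hi) edges <- c(edges, w_hi)
  lags <- unlist(lapply(pulses$times, function(p) {
    d <- times - p
    d[d >= params$window[1] & d < w_hi]
  }), use.names = FALSE)
  counts <- if (length(lags))
    graphics::hist(lags, breaks = edges, plot = FALSE)$counts
  else numeric(length(edges) - 1)
  # Gaussian smoothing, truncated at +/- 4 sd, renormalized
  half <- ceiling(4 * params$kernel_sd / params$bin)
  kx <- (-half:half) * params$bin
  kern <- dnorm(kx, sd = params$kernel_sd)
  kern <- kern / sum(kern)
  padded <- c(numeric(half), counts, numeric(half))
  smoothed <- vapply(seq_along(counts), function(i)
    sum(padded[i:(i + 2 * half)] * rev(kern)), numeric(1))
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  widths <- diff(edges)
  n_pulses <- length(pulses$times)
  structure(list(lag = centers,
                 rate = 1000 * smoothed / (n_pulses * widths),
                 per_pulse = smoothed / n_pulses,
                 n_pulses = n_pulses, n_spikes = length(lags),
                 bin = params$bin, window = c(params$window[1], w_hi)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: window [%g, %g] ms, %d pulses, %d spikes (%.3f per pulse)\n",
              x$window[1], x$window[2], x$n_pulses, x$n_spikes,
              x$n_spikes / x$n_pulses))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  plot(x$lag, x$rate, type = "l", xlab = "lag after pulse (ms)",
       ylab = "rate (spikes/s per pulse)", ...)
}

#' Coefficient of determination between two sampled curves
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' mean of the reference curve. Used to compare a model-simulated PSTH (or
#' spectrum) against a reference.
#'
#' @param model,reference Numeric vectors on the same grid.
#' @return The R-squared statistic (1 for identical curves, 0 for a model
#'   equal to the reference mean).
#' @export
r_squared <- function(model, reference) {
  if (length(model) != length(reference))
    stop("curves must be sampled on the same grid", call. = FALSE)
  ss_tot <- sum((reference - mean(reference))^2)
  1 - sum((reference - model)^2) / ss_tot
}

#' Compare a simulated PSTH against an external recording
#'
#' Computes both PSTHs on a common bin grid and returns the R-squared of the
#' model curve against the reference curve.
#'
#' @param model_spikes,reference_spikes Spike times ([spike_trains] or
#'   numeric ms vectors).
#' @param pulses The common [pulse_train].
#' @param params A [psth_params] object.
#' @return List with `r_squared`, `model` and `reference` [compute_psth()]
#'   results.
#' @export
psth_compare <- function(model_spikes, reference_spikes, pulses,
                         params = psth_params()) {
  m <- compute_psth(model_spikes, pulses, params)
  r <- compute_psth(reference_spikes, pulses, params)
  list(r_squared = r_squared(m$rate, r$rate), model = m, reference = r)
}
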