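#' Plain-text I/O for signals, spikes and fitted objects
#'
#' All artifacts use small plain-text formats: pulse/spike trains as CSV of
#' times in ms, sampled signals as two-column CSVs, the fitted biomarker as
#' JSON, and control traces as CSV plus a JSON summary.
#'
#' @param x Object to write.
#' @param path File path.
#' @name dbsloop-io
NULL

#' @rdname dbsloop-io
#' @export
write_pulse_csv <- function(x, path) {
  stopifnot(inherits(x, "pulse_train"))
  write.csv(data.frame(time_ms = x$times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dbsloop-io
#' @param duration Span (ms) of the train being read (needed because an
#'   event list does not carry it).
#' @export
read_pulse_csv <- function(path, duration) {
  as_pulse_train(read.csv(path)$time_ms, duration = duration)
}

#' @rdname dbsloop-io
#' @export
write_rate_csv <- function(x, path) {
  stopifnot(inherits(x, "rate_signal"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dbsloop-io
#' @export
read_rate_csv <- function(path) {
  d <- read.csv(path)
  rate_signal(d$rate_hz, dt = d$time_ms[2] - d$time_ms[1])
}

#' @rdname dbsloop-io
#' @param meta Optional named list stored in the JSON sidecar alongside `fs`,
#'   `kind` and `n` (e.g. seed, DBS frequency).
#' @export
write_emg_csv <- function(x, path, meta = list()) {
  stopifnot(inherits(x, "emg_signal"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  side <- c(list(fs = x$fs, kind = x$kind, n = length(x$values)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname dbsloop-io
#' @export
read_emg_csv <- function(path) {
  d <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  emg_signal(d$emg_mV, fs = side$fs, kind = side$kind)
}

#' @rdname dbsloop-io
#' @export
write_spikes_csv <- function(x, path) {
  stopifnot(inherits(x, "spike_trains"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dbsloop-io
#' @param n_neurons Population size (ids without spikes are kept as empty
#'   trains).
#' @param population Population label.
#' @export
read_spikes_csv <- function(path, duration, n_neurons = NULL,
                            population = "neurons") {
  d <- read.csv(path)
  if (is.null(n_neurons)) n_neurons <- max(d$neuron_id)
  trains <- split(d$time_ms, factor(d$neuron_id, levels = seq_len(n_neurons)))
  spike_trains(lapply(trains, function(v) sort(as.numeric(v))),
               duration = duration, population = population)
}

#' @rdname dbsloop-io
#' @export
write_biomarker_json <- function(x, path) {
  stopifnot(inherits(x, "emg_biomarker"))
  keep <- x[c("order", "coefficients", "beta_orth", "standardization",
              "zeta_range", "noise_sd", "fitted_freqs", "fs", "lag",
              "r_squared", "residual_sd", "n_obs")]
  keep$poly_coefs <- list(alpha = x$poly_coefs$alpha,
                          norm2 = x$poly_coefs$norm2)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname dbsloop-io
#' @export
read_biomarker_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- stats::setNames(unlist(raw$coefficients),
                                      paste0("phi_", 0:raw$order))
  raw$standardization <- as.list(raw$standardization)
  raw$poly_coefs <- list(alpha = as.numeric(raw$poly_coefs$alpha),
                         norm2 = as.numeric(raw$poly_coefs$norm2))
  raw$training <- NULL
  structure(raw, class = "emg_biomarker")
}

#' @rdname dbsloop-io
#' @export
write_control_trace <- function(x, path) {
  stopifnot(inherits(x, "control_trace"))
  write.csv(as.data.frame(unclass(x)[c("t_min", "u_hz", "z", "e")]), path,
            row.names = FALSE)
  summary <- list(beta_z = attr(x, "beta_z"),
                  noise_band = attr(x, "noise_band"),
                  converged = attr(x, "converged"),
                  settling_time = attr(x, "settling_time"),
                  u_final = x$u_hz[nrow(x)])
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname dbsloop-io
#' @param dt Sample interval (ms) of the current trace.
#' @export
write_current_csv <- function(x, path, dt = 0.1) {
  write.csv(data.frame(time_ms = (seq_along(x) - 1) * dt, current_nA = x),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname dbsloop-io
#' @param y An [emg_signal] to export a spectrogram of.
#' @param params A [spectral_params] object.
#' @export
write_spectrogram_csv <- function(y, path, params = spectral_params()) {
  t_grid <- seq(0, params$T_eval, by = params$hop)
  p <- power_density(y, params$band, t_grid, params)
  d <- data.frame(t_s = rep(t_grid, times = length(params$band)),
                  f_hz = rep(params$band, each = length(t_grid)),
                  p = as.vector(p))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
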