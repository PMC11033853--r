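#' Spectral system-output parameters
#'
#' The controlled variable of the closed loop is a Hann-windowed short-time
#' power measure of the (estimated) EMG: the power density `p(f, t)` at
#' integer frequencies across the analysis band, its time integral (band
#' power) over an initial horizon, and the scalar system output `z(u)` (the
#' mean over the horizon of the power density summed over the band).
#'
#' @param window_w Window width (s). Its 1-s default matches the 1-Hz band
#'   spacing, so integer frequencies fall on the window's natural resolution.
#' @param fs Sampling rate of the analysed EMG (Hz); Nyquist must exceed the
#'   band edge.
#' @param band Integer analysis frequencies (Hz), default `2:200`.
#' @param T_eval Evaluation horizon (s), default 5.
#' @param hop Spacing of the time grid for the `t` integrals (s).
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(window_w = 1, fs = 500, band = 2:200, T_eval = 5,
                            hop = 0.01) {
  if (window_w > T_eval) stop("`window_w` must not exceed `T_eval`",
                              call. = FALSE)
  if (max(band) >= fs / 2)
    stop("analysis band must lie below the Nyquist frequency", call. = FALSE)
  if (min(band) <= 0) stop("analysis band must be positive", call. = FALSE)
  structure(list(window_w = window_w, fs = fs, band = as.numeric(band),
                 T_eval = T_eval, hop = hop),
            class = "spectral_params")
}

#' Hann window weight
#'
#' `H(s) = (1 + cos(2 pi s / w)) / 2` for `|s| <= w / 2`.
#'
#' @param s Offset from the window centre (s).
#' @param w Window width (s).
#' @return Window weight in `[0, 1]`.
#' @export
hann_weight <- function(s, w = 1) {
  if (any(abs(s) > w / 2 + 1e-12))
    stop("|s| must not exceed w/2", call. = FALSE)
  0.5 * (1 + cos(2 * pi * s / w))
}

# Short-time Hann-windowed power at the given frequencies and window centres.
# Riemann discretization of p = (1/w) |int y(t+s) H(s) exp(i 2 pi f s) ds|^2
# with ds = 1/fs; the signal is zero-padded by w/2 on both sides so that the
# published limits t in [0, T] remain usable at the edges.
stft_power <- function(values, freqs, t_centers, fs, w) {
  n_half <- round(w * fs / 2)
  s <- (seq_len(2 * n_half + 1) - 1 - n_half) / fs
  H <- hann_weight(s, w)
  pad <- c(numeric(n_half + 1), values, numeric(n_half + 1))
  start <- round(t_centers * fs) + 1        # padded index of s = -w/2 is start+1
  seg_idx <- outer(start, seq_len(2 * n_half + 1), `+`)
  S <- matrix(pad[seg_idx], nrow = length(t_centers))
  basis <- exp(1i * 2 * pi * outer(s, freqs))    # (2n_half+1) x n_freq
  ft <- (S %*% (H * basis)) / fs
  (Mod(ft)^2) / w
}

#' Hann-windowed power density of an EMG signal
#'
#' @param y An [emg_signal] (or numeric vector at `params$fs`).
#' @param f Frequencies (Hz) at which to evaluate.
#' @param t Window-centre times (s).
#' @param params A [spectral_params] object.
#' @return Matrix `length(t) x length(f)` of power densities (drops to a
#'   vector/scalar for single `t`/`f` via `drop`).
#' @export
power_density <- function(y, f, t, params = spectral_params()) {
  values <- if (inherits(y, "emg_signal")) y$values else as.numeric(y)
  drop(stft_power(values, f, t, fs = params$fs, w = params$window_w))
}

#' Band power over an initial horizon
#'
#' Time integral of the power density `p(f, t)` over `t` in `[0, T]`
#' (trapezoid rule on the hop grid).
#'
#' @inheritParams power_density
#' @param T_eval Horizon (s).
#' @return Numeric vector, one band power per frequency in `f`.
#' @export
band_power <- function(y, f, T_eval = NULL, params = spectral_params()) {
  if (is.null(T_eval)) T_eval <- params$T_eval
  t_grid <- seq(0, T_eval, by = params$hop)
  p <- stft_power(if (inherits(y, "emg_signal")) y$values else as.numeric(y),
                  f, t_grid, fs = params$fs, w = params$window_w)
  wts <- rep(params$hop, length(t_grid))
  wts[c(1, length(t_grid))] <- params$hop / 2
  drop(crossprod(wts, p))
}

#' Scalar system output z(u)
#'
#' The controlled variable: the mean over the initial horizon of the power
#' density summed over the integer analysis band,
#' `z(u) = (1/T) int_0^T sum_f p(f, t, u) dt`.
#'
#' @param y An [emg_signal], typically the estimated EMG at DBS frequency `u`.
#' @param u The DBS frequency the signal was generated at (Hz); provenance
#'   only.
#' @param params A [spectral_params] object.
#' @return An object of class `system_output`: list with `z` (mean band power
#'   density), `u`, `T_eval` and `band`.
#' @export
system_output <- function(y, u = NA_real_, params = spectral_params()) {
  values <- if (inherits(y, "emg_signal")) y$values else as.numeric(y)
  if (length(values) < params$T_eval * params$fs)
    stop("signal must cover the evaluation horizon T", call. = FALSE)
  t_grid <- seq(0, params$T_eval, by = params$hop)
  p <- stft_power(values, params$band, t_grid, fs = params$fs,
                  w = params$window_w)
  psum <- rowSums(p)
  wts <- rep(params$hop, length(t_grid))
  wts[c(1, length(t_grid))] <- params$hop / 2
  z <- sum(wts * psum) / params$T_eval
  structure(list(z = z, u = u, T_eval = params$T_eval, band = params$band),
            class = "system_output")
}

#' @export
print.system_output <- function(x, ...) {
  cat(sprintf("system output z = %.6g (u = %s Hz, band [%g, %g] Hz, T = %g s)\n",
              x$z, format(x$u), min(x$band), max(x$band), x$T_eval))
  invisible(x)
}
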