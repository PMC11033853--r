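#' Standardize a firing-rate signal
#'
#' The biomarker polynomial acts on the standardized Vim rate
#' `zeta = (x - mean(x)) / sd(x)`. When fitting, the statistics are computed
#' once on the concatenated training rates and frozen, so that the same map
#' applies consistently across DBS frequencies at inference time.
#'
#' @param x A [rate_signal] or numeric vector.
#' @param stats Optional list with `mean` and `sd` (frozen statistics). If
#'   `NULL`, computed from `x` itself.
#' @return Numeric vector of standardized values with attribute `"stats"`.
#' @export
standardize <- function(x, stats = NULL) {
  v <- if (inherits(x, "rate_signal")) x$values else as.numeric(x)
  if (is.null(stats)) stats <- list(mean = mean(v), sd = stats::sd(v))
  if (!is.finite(stats$sd) || stats$sd <= 1e-12)
    stop("cannot standardize a (near-)constant signal: sd is zero",
         call. = FALSE)
  structure((v - stats$mean) / stats$sd, stats = stats)
}

# Discrete orthogonal polynomial basis by the Forsythe three-term recurrence:
#   p_0 = 1;  p_{k+1} = (x - alpha_{k+1}) p_k - (norm2_k / norm2_{k-1}) p_{k-1}
# with alpha_{k+1} = sum(x p_k^2) / norm2_k and norm2_k = sum(p_k^2).
# Numerically stable at high degree even for heavy-tailed regressors (the
# standardized Vim rate has rare large onset-transient values), where a raw
# power basis loses all precision. Returned columns are p_k / sqrt(norm2_k).
orth_poly_fit <- function(x, degree) {
  n <- length(x)
  if (length(unique(x)) <= degree)
    stop("polynomial degree must be below the number of unique points",
         call. = FALSE)
  alpha <- numeric(degree)
  norm2 <- numeric(degree + 1)          # norm2[k + 1] = ||p_k||^2
  basis <- matrix(0, n, degree)
  p_prev <- numeric(n)
  p_cur <- rep(1, n)
  norm2[1] <- n
  for (k in seq_len(degree)) {
    alpha[k] <- sum(x * p_cur^2) / norm2[k]
    beta_k <- if (k == 1) 0 else norm2[k] / norm2[k - 1]
    p_next <- (x - alpha[k]) * p_cur - beta_k * p_prev
    norm2[k + 1] <- sum(p_next^2)
    if (norm2[k + 1] <= 0)
      stop("rank-deficient polynomial basis; reduce the order", call. = FALSE)
    basis[, k] <- p_next / sqrt(norm2[k + 1])
    p_prev <- p_cur
    p_cur <- p_next
  }
  list(basis = basis, alpha = alpha, norm2 = norm2)
}

# Evaluate the stored orthogonal basis at new points.
orth_poly_eval <- function(x, alpha, norm2) {
  degree <- length(alpha)
  basis <- matrix(0, length(x), degree)
  p_prev <- numeric(length(x))
  p_cur <- rep(1, length(x))
  for (k in seq_len(degree)) {
    beta_k <- if (k == 1) 0 else norm2[k] / norm2[k - 1]
    p_next <- (x - alpha[k]) * p_cur - beta_k * p_prev
    basis[, k] <- p_next / sqrt(norm2[k + 1])
    p_prev <- p_cur
    p_cur <- p_next
  }
  basis
}

# Monomial coefficients of the fitted polynomial: multiply the recurrence out
# in coefficient vectors to get the exact monomial representation phi_0..phi_N
# (reported for interpretability; never used for evaluation).
poly_monomial_coefs <- function(beta, alpha, norm2) {
  N <- length(alpha)
  polys <- vector("list", N + 1)
  polys[[1]] <- 1                                   # p_0
  for (k in seq_len(N)) {
    prev <- polys[[k]]
    shifted <- c(0, prev) - alpha[k] * c(prev, 0)   # (x - alpha_k) p_{k-1}
    if (k >= 2) {
      beta_k <- norm2[k] / norm2[k - 1]
      pm2 <- c(polys[[k - 1]], 0, 0)[seq_along(shifted)]
      shifted <- shifted - beta_k * pm2
    }
    polys[[k + 1]] <- shifted
  }
  phi <- numeric(N + 1)
  phi[1] <- beta[1]                                 # intercept
  for (k in seq_len(N)) {
    mono <- polys[[k + 1]] / sqrt(norm2[k + 1])
    phi[seq_along(mono)] <- phi[seq_along(mono)] + beta[k + 1] * mono
  }
  names(phi) <- paste0("phi_", 0:N)
  phi
}

#' Fit the polynomial EMG biomarker
#'
#' Least-squares fit of the order-`order` polynomial mapping the standardized
#' Vim firing rate to the simulated (reference) EMG, pooled across training
#' DBS frequencies. This is the fast surrogate used as the feedback biomarker
#' in closed-loop control: evaluating it replaces the full corticospinal
#' simulation. The standardization statistics are computed on the
#' concatenated training rates and frozen in the fitted object.
#'
#' The solve uses an orthogonal polynomial basis (raw high powers of the
#' regressor are never formed); the equivalent monomial coefficients
#' `phi_0 .. phi_N` are reported via [coef()] for interpretability, but
#' prediction always evaluates the orthogonal form.
#'
#' @param rate_by_freq Named list of [rate_signal]s, one per training DBS
#'   frequency (names are the frequencies in Hz).
#' @param emg_by_freq Named list of [emg_signal]s with matching names.
#' @param order Polynomial order (default 25, the lowest order at which the
#'   training fit converges in the source study).
#' @param noise_sd Gaussian noise sd added to estimated EMG (mV).
#' @param lag Optional lag (ms, multiple of the EMG sample step) by which the
#'   EMG trails the rate. Fitting pairs `x(t)` with `y(t + lag)` and
#'   prediction returns `psi(x(t - lag))`, so the estimate carries the same
#'   latency as the reference. Default 0 (strictly pointwise map); the
#'   full-pipeline fit uses the fixed corticospinal latency
#'   `td_cm + td_mm + tau_V` = 30 ms.
#' @return An object of class `emg_biomarker`.
#' @examples
#' # exact recovery of a degree-5 polynomial relationship
#' x <- rate_signal(20 + 10 * abs(sin(seq(0, 20, by = 0.01))), dt = 2)
#' z <- standardize(x)
#' y <- emg_signal(0.1 * z - 0.05 * z^3 + 0.01 * z^5, fs = 500)
#' fit <- fit_biomarker(list(`130` = x), list(`130` = y), order = 5)
#' summary(fit)
#' @export
fit_biomarker <- function(rate_by_freq, emg_by_freq, order = 25,
                          noise_sd = 0.038, lag = 0) {
  if (!identical(sort(names(rate_by_freq)), sort(names(emg_by_freq))))
    stop("rate and EMG maps must cover the same frequencies", call. = FALSE)
  freqs <- names(rate_by_freq)
  xs <- list(); ys <- list()
  fs <- NULL
  for (f in freqs) {
    emg <- emg_by_freq[[f]]
    stopifnot(inherits(emg, "emg_signal"))
    fs <- emg$fs
    x <- rate_by_freq[[f]]
    if (inherits(x, "rate_signal") && abs(x$dt - 1000 / fs) > 1e-9)
      x <- resample_rate(x, fs)
    xv <- if (inherits(x, "rate_signal")) x$values else as.numeric(x)
    lag_n <- as.integer(round(lag * fs / 1000))
    n <- min(length(xv) - lag_n, length(emg$values) - lag_n)
    xs[[f]] <- xv[seq_len(n)]
    ys[[f]] <- emg$values[seq_len(n) + lag_n]
  }
  x_all <- unlist(xs, use.names = FALSE)
  y_all <- unlist(ys, use.names = FALSE)
  zeta <- standardize(x_all)
  stats <- attr(zeta, "stats")
  op <- orth_poly_fit(as.numeric(zeta), order)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, op$basis), y_all)
  if (fit$rank < order + 1)
    stop("rank-deficient polynomial basis; reduce the order", call. = FALSE)
  beta <- fit$coefficients
  res <- fit$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((y_all - mean(y_all))^2)
  pc <- list(alpha = op$alpha, norm2 = op$norm2)
  structure(list(
    order = order,
    coefficients = poly_monomial_coefs(beta, pc$alpha, pc$norm2),
    beta_orth = unname(beta),
    poly_coefs = pc,
    standardization = stats,
    zeta_range = range(zeta),
    noise_sd = noise_sd,
    fitted_freqs = {
      fr <- suppressWarnings(as.numeric(freqs))
      if (anyNA(fr)) freqs else fr
    },
    fs = fs,
    lag = lag,
    r_squared = 1 - ss_res / ss_tot,
    residual_sd = sqrt(ss_res / (length(y_all) - order - 1)),
    n_obs = length(y_all),
    training = list(zeta = as.numeric(zeta), y = y_all)
  ), class = "emg_biomarker")
}

# Deterministic part of the estimated EMG for standardized input.
eval_biomarker <- function(object, zeta) {
  basis <- orth_poly_eval(zeta, object$poly_coefs$alpha,
                          object$poly_coefs$norm2)
  drop(cbind(1, basis) %*% object$beta_orth)
}

#' Predict (estimate) EMG from a Vim firing-rate signal
#'
#' Applies the fitted polynomial biomarker: standardizes the rate with the
#' frozen training statistics, evaluates the polynomial, and (optionally)
#' adds Gaussian white noise of the fitted `noise_sd`. With noise off the
#' estimate is a pure memoryless function of the rate.
#'
#' @param object A fitted [fit_biomarker()] object.
#' @param x A [rate_signal] (resampled to the training EMG rate if needed) or
#'   numeric rate vector already on that grid.
#' @param add_noise Add the Gaussian noise term (default `TRUE`).
#' @param seed Optional integer seed for the noise.
#' @param ... Unused.
#' @return An [emg_signal] of kind `"estimated"`.
#' @export
predict.emg_biomarker <- function(object, x, add_noise = TRUE, seed = NULL,
                                  ...) {
  if (inherits(x, "rate_signal") && abs(x$dt - 1000 / object$fs) > 1e-9)
    x <- resample_rate(x, object$fs)
  zeta <- standardize(x, stats = object$standardization)
  lag_n <- as.integer(round(object$lag * object$fs / 1000))
  if (lag_n > 0)
    zeta <- structure(c(rep(zeta[1], lag_n), zeta[seq_len(length(zeta) - lag_n)]),
                      stats = attr(zeta, "stats"))
  span <- diff(object$zeta_range)
  if (min(zeta) < object$zeta_range[1] - 0.2 * span ||
      max(zeta) > object$zeta_range[2] + 0.2 * span)
    warning("input rate leaves the standardized training range by >20%; ",
            "the high-order polynomial may extrapolate poorly")
  yhat <- eval_biomarker(object, as.numeric(zeta))
  if (add_noise)
    yhat <- yhat + with_seed(seed, rnorm(length(yhat), 0, object$noise_sd))
  emg_signal(yhat, fs = object$fs, kind = "estimated")
}

#' @rdname predict.emg_biomarker
#' @param est A fitted `emg_biomarker`.
#' @export
estimate_emg <- function(x, est, seed = NULL, add_noise = TRUE) {
  predict(est, x, add_noise = add_noise, seed = seed)
}

#' @export
print.emg_biomarker <- function(x, ...) {
  cat(sprintf(
    "EMG biomarker: order-%d polynomial of the standardized Vim rate\n", x$order))
  cat(sprintf("  trained on DBS frequencies: %s Hz (%d samples)\n",
              paste(x$fitted_freqs, collapse = ", "), x$n_obs))
  cat(sprintf("  training R^2 = %.4f, residual sd = %.4f mV, noise sd = %.3g mV\n",
              x$r_squared, x$residual_sd, x$noise_sd))
  invisible(x)
}

#' @export
summary.emg_biomarker <- function(object, ...) {
  structure(list(fit = object), class = "summary.emg_biomarker")
}

#' @export
print.summary.emg_biomarker <- function(x, ...) {
  print(x$fit)
  s <- x$fit$standardization
  cat(sprintf("  standardization: mean %.3f Hz, sd %.3f Hz; zeta in [%.2f, %.2f]\n",
              s$mean, s$sd, x$fit$zeta_range[1], x$fit$zeta_range[2]))
  cat("  leading monomial coefficients:\n")
  print(utils::head(x$fit$coefficients, 6))
  invisible(x)
}

#' @export
coef.emg_biomarker <- function(object, ...) object$coefficients

#' @export
residuals.emg_biomarker <- function(object, ...) {
  object$training$y - eval_biomarker(object, object$training$zeta)
}

#' @export
fitted.emg_biomarker <- function(object, ...) {
  eval_biomarker(object, object$training$zeta)
}

#' @export
plot.emg_biomarker <- function(x, n_grid = 400, ...) {
  zg <- seq(x$zeta_range[1], x$zeta_range[2], length.out = n_grid)
  sub <- sample(length(x$training$zeta), min(5000, length(x$training$zeta)))
  plot(x$training$zeta[sub], x$training$y[sub], pch = ".", col = "grey50",
       xlab = "standardized Vim rate", ylab = "EMG (mV)", ...)
  lines(zg, eval_biomarker(x, zg), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.emg_biomarker <- function(object, nsim = 1, seed = NULL, x, ...) {
  with_seed(seed, {
    base <- predict(object, x, add_noise = FALSE)
    out <- replicate(nsim,
      base$values + rnorm(length(base$values), 0, object$noise_sd))
    as.data.frame(out)
  })
}

#' Training R-squared as a function of polynomial order
#'
#' Refits the biomarker at every order up to `max_order` on the stored
#' training data. Training R-squared is non-decreasing in the order (nested
#' least squares); the returned knee is the smallest order whose R-squared
#' is within `tol` of the maximum, i.e. where the fit has converged.
#'
#' @param fit A fitted [fit_biomarker()] object.
#' @param max_order Largest order to evaluate (default: the fitted order).
#' @param tol Convergence tolerance on R-squared for the knee.
#' @return Data frame with columns `order` and `r_squared`, with attribute
#'   `"knee"`.
#' @export
order_selection_curve <- function(fit, max_order = fit$order, tol = 1e-3) {
  zeta <- fit$training$zeta; y <- fit$training$y
  ss_tot <- sum((y - mean(y))^2)
  basis <- orth_poly_fit(zeta, max_order)$basis
  r2 <- vapply(seq_len(max_order), function(k) {
    f <- stats::lm.fit(cbind(1, basis[, seq_len(k), drop = FALSE]), y)
    1 - sum(f$residuals^2) / ss_tot
  }, numeric(1))
  out <- data.frame(order = seq_len(max_order), r_squared = r2)
  attr(out, "knee") <- which(r2 >= max(r2) - tol)[1]
  out
}
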