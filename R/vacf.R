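#' Velocity autocorrelation function of an ensemble
#'
#' Estimates \eqn{\mathrm{VACF}(\tau) = \langle v_i(t+\tau)\,
#' v_i(t)\rangle_{i,t}} from signed velocity series, averaging over all
#' platelets (records) and admissible time origins. Pairs never straddle
#' record boundaries, so trajectories split into segments by
#' [exclusion_filter()] contribute no spurious cross-boundary products.
#' Signed velocities are essential here: the autocorrelation of
#' magnitudes would plateau near the squared mean speed instead of
#' decaying to the noise floor that defines the memory time.
#'
#' @param ve A `"velocity_ensemble"` (see [extract_velocities()]).
#' @param lags Lags in seconds, multiples of the ensemble's sampling
#'   interval, or (default) a number `max_lag` of consecutive lags
#'   `0, dt, ..., max_lag*dt`.
#' @param max_lag Number of lags when `lags` is not given. Default 100.
#' @return An object of class `"vacf_curve"`: data frame with `lag` (s),
#'   `value` (m^2/s^2) and `n_pairs`. Lag 0 is the velocity second
#'   moment of the ensemble. Lags longer than the longest record are
#'   dropped with a warning.
#' @export
vacf <- function(ve, lags = NULL, max_lag = 100L) {
  stopifnot(inherits(ve, "velocity_ensemble"))
  dt <- ve$dt
  if (is.null(lags)) {
    ks <- 0:max_lag
  } else {
    ks <- round(lags / dt)
    if (any(abs(ks * dt - lags) > 1e-9)) {
      stop("'lags' must be multiples of the sampling interval ", dt, " s")
    }
  }
  ks <- sort(unique(as.integer(ks)))
  nmax <- max(lengths(ve$v))
  drop <- ks >= nmax
  if (any(drop)) {
    warning(sum(drop), " lag(s) beyond the longest record were dropped")
    ks <- ks[!drop]
  }
  if (length(ks) == 0L) stop("no usable lags")
  kmax <- max(ks)
  sums <- numeric(kmax + 1L)
  pairs <- numeric(kmax + 1L)
  for (x in ve$v) {
    n <- length(x)
    km <- min(kmax, n - 1L)
    # autocovariance (uncentred) via stats::acf; c_k = sum(x_t x_{t+k}) / n
    ac <- stats::acf(x, lag.max = km, type = "covariance",
                     demean = FALSE, plot = FALSE)$acf[, 1L, 1L]
    idx <- 0:km
    sums[idx + 1L] <- sums[idx + 1L] + ac * n
    pairs[idx + 1L] <- pairs[idx + 1L] + (n - idx)
  }
  value <- sums[ks + 1L] / pairs[ks + 1L]
  structure(data.frame(lag = ks * dt, value = value,
                       n_pairs = pairs[ks + 1L]),
            class = c("vacf_curve", "data.frame"))
}

#' Power-law fit of a VACF curve
#'
#' Least-squares fit of \eqn{\ln \mathrm{VACF}} on \eqn{\ln \tau} inside a
#' lag window, with \eqn{\tau} expressed in milliseconds, modelling
#' \eqn{\mathrm{VACF}(\tau) = a\,\tau^{-b}}. The amplitude `a` is the
#' VACF value at \eqn{\tau = 1} ms. Non-positive VACF values (noise-floor
#' crossings) are excluded before fitting.
#'
#' @param curve A `"vacf_curve"` from [vacf()] or [synth_vacf()].
#' @param fit_window Two lags in seconds, the fitted interval (inclusive).
#' @return An object of class `"vacf_fit"`: list with `a`, `b`, `sd_a`,
#'   `sd_b` (standard errors), `n_points` and the window.
#' @export
fit_vacf_powerlaw <- function(curve, fit_window) {
  stopifnot(inherits(curve, "vacf_curve"), length(fit_window) == 2L)
  sel <- curve$lag >= fit_window[1L] & curve$lag <= fit_window[2L] &
    curve$value > 0 & curve$lag > 0
  if (sum(sel) < 3L) {
    stop("need at least 3 strictly positive VACF values in the window")
  }
  tau_ms <- curve$lag[sel] * 1e3
  fit <- stats::lm(log(curve$value[sel]) ~ log(tau_ms))
  sm <- summary(fit)$coefficients
  structure(
    list(a = exp(sm[1L, 1L]), b = -sm[2L, 1L],
         sd_a = exp(sm[1L, 1L]) * sm[1L, 2L], sd_b = sm[2L, 2L],
         n_points = sum(sel), fit_window = fit_window),
    class = "vacf_fit")
}

#' @export
print.vacf_fit <- function(x, ...) {
  cat("VACF power-law fit: VACF(tau) = a * tau^-b  (tau in ms)\n")
  cat(sprintf("  a = %.4g (SE %.2g)   b = %.4g (SE %.2g)   [%d points]\n",
              x$a, x$sd_a, x$b, x$sd_b, x$n_points))
  invisible(x)
}

#' @export
coef.vacf_fit <- function(object, ...) c(a = object$a, b = object$b)

#' Velocity decorrelation time from a VACF curve
#'
#' The memory time \eqn{\Delta t} after which the velocity can be treated
#' as randomised: the noise floor \eqn{\sigma} is estimated as the
#' standard deviation of the VACF values inside a tail window of lags
#' where the correlation has died out, and \eqn{\Delta t} is the smallest
#' lag at which the VACF has fallen to or below \eqn{\sigma}. \eqn{\Delta
#' t} sets the update interval of the surrogate random walk
#' ([simulate_walk()]).
#'
#' @param curve A `"vacf_curve"`.
#' @param tail_window Two lags in seconds delimiting the noise-floor
#'   region; must contain at least 5 curve points. Default: the last
#'   quarter of the available lags.
#' @return An object of class `"decorrelation_result"`: list with
#'   `delta_t` (s), `sigma_tail` (m^2/s^2) and `tail_window`.
#' @export
decorrelation_time <- function(curve, tail_window = NULL) {
  stopifnot(inherits(curve, "vacf_curve"))
  lag_max <- max(curve$lag)
  if (is.null(tail_window)) tail_window <- c(0.75 * lag_max, lag_max)
  sel <- curve$lag >= tail_window[1L] & curve$lag <= tail_window[2L]
  if (sum(sel) < 5L) stop("tail window must contain at least 5 points")
  sigma <- stats::sd(curve$value[sel])
  pos <- curve$lag > 0
  below <- pos & curve$value <= sigma
  if (!any(below)) {
    stop("VACF never falls to the noise floor; extend the lag range")
  }
  structure(
    list(delta_t = min(curve$lag[below]), sigma_tail = sigma,
         tail_window = tail_window),
    class = "decorrelation_result")
}

#' @export
print.decorrelation_result <- function(x, ...) {
  cat(sprintf(
    "Velocity decorrelation time: %.4g s (noise floor sigma = %.3g m^2/s^2, window [%.3g, %.3g] s)\n",
    x$delta_t, x$sigma_tail, x$tail_window[1L], x$tail_window[2L]))
  invisible(x)
}
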