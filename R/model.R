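# Six-parameter generative model for waking heart rate: circadian cosinor
# mean plus linear activity effect, with an exact AR(1) Gaussian likelihood
# over gappy 5-minute observations.

PARAM_NAMES <- c("a", "b", "c", "d", "sigma", "k")

#' Model parameters for the heart-rate model
#'
#' Bundles the six fitted quantities: basal HR `a` (bpm), circadian amplitude
#' `b` (bpm), clock time of the circadian HR minimum `c` (hours, wrapped to
#' `[0,24)`), HR increase per unit activity `d` (bpm per step/min),
#' innovation s.d. `sigma` (bpm), and AR(1) carry-over fraction `k` per
#' 5-minute bin.
#'
#' @param a basal heart rate, bpm.
#' @param b circadian amplitude, bpm; must be `>= 0`.
#' @param c clock time of the circadian HR minimum, hours; wrapped to
#'   `[0, 24)`.
#' @param d heart-rate increase per unit activity, bpm per (steps/min).
#' @param sigma innovation standard deviation, bpm; must be `> 0`.
#' @param k AR(1) carry-over fraction per bin, in `[0, 1)`.
#' @return a named numeric vector of class `"crhr_params"`.
#' @examples
#' crhr_params(a = 73.5, b = 4, c = 3.3, d = 0.32, sigma = 6.9, k = 0.93)
#' @export
crhr_params <- function(a, b, c, d, sigma, k) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            is.numeric(sigma), is.numeric(k))
  if (b < 0) stop("amplitude b must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (k < 0 || k >= 1) stop("k must lie in [0, 1)")
  structure(c(a = unname(a), b = unname(b), c = wrap_hours(unname(c)),
              d = unname(d), sigma = unname(sigma), k = unname(k)),
            class = "crhr_params")
}

#' @export
print.crhr_params <- function(x, digits = 4, ...) {
  cat("Heart-rate model parameters:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

as_param_vector <- function(params) {
  p <- unclass(params)
  if (!is.null(names(p))) p <- p[PARAM_NAMES]
  if (length(p) != 6L || anyNA(p)) stop("params must supply a, b, c, d, sigma, k")
  as.numeric(p)
}

#' Model mean heart rate
#'
#' The deterministic part of the model:
#' `a - b * cos(pi/12 * (t - c)) + d * steps_per_min`.  Exactly 24-h periodic
#' in `t`; minimized at `t = c (mod 24)` when activity is constant.
#'
#' @param params a [crhr_params] object (or named vector with the six fields).
#' @param t time in hours (any real; hours since local midnight of the
#'   window's first day by convention).
#' @param steps_per_min activity rate, steps per minute.
#' @return mean heart rate, bpm (vectorized over `t`/`steps_per_min`).
#' @export
mean_hr <- function(params, t, steps_per_min = 0) {
  p <- as_param_vector(params)
  p[1] - p[2] * cos(pi / 12 * (t - p[3])) + p[4] * steps_per_min
}

#' Observation series for one fit window
#'
#' A gappy series of waking observations on the 5-minute grid: times in
#' hours (strictly increasing, integer multiples of the bin length apart),
#' observed heart rate and step rate.
#'
#' @param t hours since local midnight of the window's first day.
#' @param hr observed heart rate, bpm.
#' @param steps_per_min step rate, steps per minute.
#' @param bin_minutes grid resolution in minutes (default 5).
#' @return a `data.frame` of class `"gap_series"` with attribute
#'   `bin_minutes`.
#' @export
gap_series <- function(t, hr, steps_per_min, bin_minutes = 5) {
  stopifnot(length(t) == length(hr), length(t) == length(steps_per_min))
  if (length(t) && any(diff(t) <= 0)) stop("t must be strictly increasing")
  bl <- bin_minutes / 60
  if (length(t) > 1) {
    g <- diff(t) / bl
    if (any(abs(g - round(g)) > 1e-6))
      stop("consecutive t must be integer multiples of the bin length apart")
  }
  structure(data.frame(t = t, hr = hr, steps_per_min = steps_per_min),
            bin_minutes = bin_minutes, class = c("gap_series", "data.frame"))
}

gap_bins <- function(obs) {
  bl <- (attr(obs, "bin_minutes") %||% 5) / 60
  if (nrow(obs) < 2) return(integer(0))
  pmax(1L, as.integer(round(diff(obs$t) / bl)))
}

#' Exact AR(1) log-likelihood over a gappy series
#'
#' Gaussian log-likelihood of the residuals
#' `r_i = hr_i - mean_hr(params, t_i, x_i)` under the stationary AR(1)
#' process observed at the given (possibly gapped) bin times.  The first
#' residual uses the stationary marginal `N(0, sigma^2/(1-k^2))`; a residual
#' following a gap of `g` bins is conditionally
#' `N(k^g r_prev, sigma^2 (1-k^(2g))/(1-k^2))`, so large charging gaps are
#' handled exactly rather than dropped.
#'
#' Invalid parameters (`sigma <= 0`, `k` outside `[0,1)`, `b < 0`) return
#' `-Inf` rather than signalling an error, so samplers can reject them.
#'
#' @param params a [crhr_params] object or named vector.
#' @param obs a [gap_series].
#' @return the log-density (scalar).
#' @export
ar1_loglik <- function(params, obs) {
  as.numeric(ar1_loglik_mat(matrix(as_param_vector(params), nrow = 1), obs))
}

# Vectorized over parameter sets: theta is a (n_sets x 6) matrix with columns
# a, b, c, d, sigma, k.  Returns one log-density per row.  This is the hot
# path of the ensemble sampler, so everything is matrix algebra over rows =
# observations, columns = parameter sets.
ar1_loglik_mat <- function(theta, obs) {
  stopifnot(is.matrix(theta), ncol(theta) == 6)
  n <- nrow(obs); W <- nrow(theta)
  if (n < 1) stop("obs must be non-empty")
  a <- theta[, 1]; b <- theta[, 2]; cc <- theta[, 3]
  d <- theta[, 4]; sg <- theta[, 5]; k <- theta[, 6]
  ok <- b >= 0 & sg > 0 & k >= 0 & k < 1
  out <- rep(-Inf, W)
  if (!any(ok)) return(out)

  t <- obs$t; y <- obs$hr; x <- obs$steps_per_min
  # residual matrix (n x W): y - [a - b cos(pi/12 (t - c)) + d x]
  ct <- cos(pi / 12 * outer(t, cc, "-"))
  r <- (y - outer(x, d)) - matrix(a, n, W, byrow = TRUE) +
    ct * matrix(b, n, W, byrow = TRUE)

  vstat <- sg^2 / (1 - k^2)                      # stationary variance
  ll <- -0.5 * (log(2 * pi * vstat) + r[1, ]^2 / vstat)
  if (n > 1) {
    g <- gap_bins(obs)
    logk <- ifelse(k > 0, log(k), -Inf)
    Kg <- exp(outer(g, logk))                    # k^g, (n-1) x W; 0^g -> 0
    e <- r[-1, , drop = FALSE] - Kg * r[-n, , drop = FALSE]
    V <- matrix(vstat, n - 1, W, byrow = TRUE) * (1 - Kg^2)
    ll <- ll - 0.5 * colSums(log(2 * pi * V) + e^2 / V)
  }
  out[ok] <- ll[ok]
  out[is.na(out)] <- -Inf
  out
}

#' Decorrelation time of the AR(1) noise
#'
#' The e-folding time of the residual autocorrelation,
#' `-bin_minutes / log(k)`.  At the population-typical `k = 0.9339` per
#' 5-minute bin this is about 73 minutes — the roughly one-hour correlated
#' error process attributed to hormonal dynamics such as cortisol.
#'
#' @param k AR(1) carry-over fraction per bin, in `(0, 1)`.
#' @param bin_minutes bin length in minutes (default 5).
#' @return decorrelation time in minutes.
#' @examples
#' decorrelation_time(0.9339) # ~73 min
#' @export
decorrelation_time <- function(k, bin_minutes = 5) {
  if (any(k <= 0 | k >= 1)) stop("k must lie strictly in (0, 1)")
  -bin_minutes / log(k)
}
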