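# Day-to-day phase tracking: each 2-day window is fit in time order, with
# the previous window's phase (plus 1 h of Gaussian width) as a circular
# prior on c, and the posterior sampled instead of the likelihood.

#' Track circadian phase across successive windows
#'
#' Fits every window in time order.  The first window uses `base_prior`
#' (flat in phase); each subsequent window gets a circular Gaussian prior on
#' `c` centered at the previous window's posterior circular-mean phase with
#' s.d. `prior_sd_hours` (default 1 h).  All other parameters keep
#' `base_prior`.  If a window fails its sampler diagnostics it is flagged
#' and the chain restarts from `base_prior` at the next window.
#'
#' The phase difference reported for each window is the wrapped difference
#' (hours, in `(-12, 12]`) between the estimated HR phase — the circadian
#' minimum of HR — and the clock hour of the center sleep's midpoint.
#'
#' @param windows a `crhr_windows` list, time-ordered.
#' @param base_prior a [crhr_prior] used for the first window and for all
#'   non-phase parameters.
#' @param n_total_samples MCMC budget per window (default 100000).
#' @param prior_sd_hours s.d. of the sequential phase prior (default 1).
#' @param seed integer; per-window seeds are derived from it.
#' @param keep_fits keep each window's `crhr_fit` (without samples) on the
#'   track (default `TRUE`).
#' @param ... further arguments to [fit_window] (e.g. `n_walkers`).
#' @return an object of class `"crhr_track"`: a `data.frame` with one row
#'   per window (`date`, `sleep_midpoint`, `sleep_midpoint_h`,
#'   `phase_mean_h`, `ci80_lo`, `ci80_hi`, `phase_difference_h`, `n_obs`,
#'   `flagged`) plus the per-window fits as an attribute.
#' @export
track_phases <- function(windows, base_prior = crhr_prior(),
                         n_total_samples = 100000, prior_sd_hours = 1,
                         seed = NULL, keep_fits = TRUE, ...) {
  n <- length(windows)
  if (n == 0) stop("no windows to track")
  if (is.null(seed)) seed <- 1L
  rows <- vector("list", n)
  fits <- vector("list", n)
  prev_phase <- NULL
  for (i in seq_len(n)) {
    w <- windows[[i]]
    prior_i <- if (is.null(prev_phase)) base_prior else
      crhr_prior(bounds = base_prior$bounds,
                 c_prior = c(prev_phase, prior_sd_hours))
    fit <- tryCatch(
      fit_window(w, prior = prior_i, n_total_samples = n_total_samples,
                 seed = (seed + i) %% .Machine$integer.max,
                 keep_samples = FALSE, ...),
      error = function(e) e)
    flagged <- inherits(fit, "error")
    if (flagged) {
      warning(sprintf("window %d flagged (%s); tracking chain restarted",
                      i, conditionMessage(fit)))
      prev_phase <- NULL
      rows[[i]] <- data.frame(
        date = format(w$midnight1, "%Y-%m-%d"),
        sleep_midpoint = w$center_sleep$midpoint,
        sleep_midpoint_h = clock_hours(w$center_sleep$midpoint),
        phase_mean_h = NA_real_, ci80_lo = NA_real_, ci80_hi = NA_real_,
        phase_difference_h = NA_real_,
        n_obs = nrow(w$observations), flagged = TRUE)
      next
    }
    s <- fit$summary
    ph <- s$mean[s$param == "c"]
    mid_h <- clock_hours(w$center_sleep$midpoint)
    rows[[i]] <- data.frame(
      date = format(w$midnight1, "%Y-%m-%d"),
      sleep_midpoint = w$center_sleep$midpoint,
      sleep_midpoint_h = mid_h,
      phase_mean_h = ph,
      ci80_lo = s$lo80[s$param == "c"],
      ci80_hi = s$hi80[s$param == "c"],
      phase_difference_h = wrap_diff(ph, mid_h),
      n_obs = nrow(w$observations), flagged = FALSE)
    fits[[i]] <- fit
    prev_phase <- ph
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- if (keep_fits) fits else NULL
  attr(out, "prior_sd_hours") <- prior_sd_hours
  class(out) <- c("crhr_track", "data.frame")
  out
}

#' @export
print.crhr_track <- function(x, digits = 3, ...) {
  cat(sprintf("Phase track: %d window(s), %d flagged\n",
              nrow(x), sum(x$flagged)))
  print.data.frame(
    x[, c("date", "sleep_midpoint_h", "phase_mean_h", "ci80_lo", "ci80_hi",
          "phase_difference_h")],
    digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot a phase track
#'
#' Phase estimates with the 80% band over sleep midpoints, by date.
#'
#' @param x a `crhr_track`.
#' @param ... passed to [plot()].
#' @export
plot.crhr_track <- function(x, ...) {
  d <- seq_len(nrow(x))
  ph <- x$phase_mean_h
  plot(d, ph, type = "n", ylim = c(0, 24), xlab = "window",
       ylab = "clock hour", yaxs = "i", ...)
  # unwrap the band around the point estimate so the polygon is contiguous
  lo <- ph - wrap_hours(ph - x$ci80_lo)
  hi <- ph + wrap_hours(x$ci80_hi - ph)
  polygon(c(d, rev(d)), c(lo, rev(hi)), col = rgb(1, 0, 0, 0.2), border = NA)
  lines(d, ph, col = "red", lwd = 2)
  points(d, x$sleep_midpoint_h, pch = 4, col = "grey40")
  legend("topright", legend = c("phase (80% band)", "sleep midpoint"),
         col = c("red", "grey40"), pch = c(NA, 4), lty = c(1, NA), bty = "n")
  invisible(x)
}

#' Export a phase track to CSV
#'
#' @param track a `crhr_track`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_phase_track <- function(track, path) {
  out <- data.frame(
    date = track$date,
    phase_mean_h = track$phase_mean_h,
    ci80_lo = track$ci80_lo,
    ci80_hi = track$ci80_hi,
    sleep_midpoint_h = track$sleep_midpoint_h,
    phase_difference_h = track$phase_difference_h)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Partial autocorrelation with significance bounds
#'
#' PACF of a real series via the Durbin-Levinson recursion on the sample
#' autocorrelations, with two-sided 95% white-noise bounds
#' `+/- z_0.975 / sqrt(n)` — the convention used to judge how many days into
#' the future phase differences remain predictive.
#'
#' @param series numeric vector (length `> max_lag + 1`).
#' @param max_lag maximum lag (default 15).
#' @return `data.frame(lag, pacf, lower, upper)`.
#' @export
pacf_with_bounds <- function(series, max_lag = 15) {
  series <- as.numeric(series)
  n <- length(series)
  if (n <= max_lag + 1) stop("series too short for max_lag")
  if (sd(series) == 0) stop("PACF undefined for a constant series")
  rho <- as.numeric(acf(series, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  phi <- matrix(0, max_lag, max_lag)
  phi[1, 1] <- rho[1]
  if (max_lag >= 2) {
    for (k in 2:max_lag) {
      num <- rho[k] - sum(phi[k - 1, 1:(k - 1)] * rho[(k - 1):1])
      den <- 1 - sum(phi[k - 1, 1:(k - 1)] * rho[1:(k - 1)])
      phi[k, k] <- num / den
      phi[k, 1:(k - 1)] <- phi[k - 1, 1:(k - 1)] -
        phi[k, k] * phi[k - 1, (k - 1):1]
    }
  }
  b <- qnorm(0.975) / sqrt(n)
  data.frame(lag = seq_len(max_lag), pacf = diag(phi),
             lower = -b, upper = b)
}
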