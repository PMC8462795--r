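# Personalized phase-response curve (PRC) of the heart-rate clock to
# activity: activity is re-timed relative to the previous night's circadian
# phase, binned into 24 one-hour relative bins, regressed against the
# night-to-night phase shift, and summarized by a 4-parameter asymmetric
# sinusoid whose vertical offset yields the intrinsic period.

#' Collect PRC regression points
#'
#' For each day flanked by two phase estimates: activity is shifted by the
#' previous night's phase so bin timing is relative to the circadian HR
#' minimum (relative hour 0), then totalled into 24 one-hour bins.  Each
#' day contributes one point `(x_h, y)` to every bin `h`: `x_h` the day's
#' total steps in relative hour `h` (possibly 0), `y` the wrapped phase
#' shift from the previous night to the following night (hours; advance
#' positive, delay negative).  Days missing either flanking phase are
#' skipped.
#'
#' @param track a `crhr_track` (or any data.frame with `sleep_midpoint` and
#'   `phase_mean_h`), time-ordered.
#' @param binned the `crhr_binned` series the track was computed from.
#' @param lag nights between the two phase estimates (1 = consecutive
#'   nights; 2 = the non-overlapping robustness variant).
#' @return `data.frame(day, rel_hour, x, y)` of class `"prc_points"`, with
#'   attributes `n_days` and `mean_daily_steps`.
#' @export
collect_prc_points <- function(track, binned, lag = 1) {
  stopifnot(lag >= 1)
  n <- nrow(track)
  if (n < lag + 1) stop("track too short: need at least ", lag + 1, " nights")
  bin_minutes <- attr(binned, "bin_minutes") %||% 5
  bs <- as.numeric(binned$bin_start)
  hod <- clock_hours(binned$bin_start)
  steps <- binned$steps_per_min * bin_minutes

  out <- list(); daily_steps <- numeric(0); skipped <- 0L
  for (i in seq_len(n - lag)) {
    p1 <- track$phase_mean_h[i]
    p2 <- track$phase_mean_h[i + lag]
    if (is.na(p1) || is.na(p2)) { skipped <- skipped + 1L; next }
    span <- bs >= as.numeric(track$sleep_midpoint[i]) &
      bs < as.numeric(track$sleep_midpoint[i + 1])
    rel <- floor(wrap_hours(hod[span] - p1))
    x <- vapply(0:23, function(h) sum(steps[span][rel == h]), numeric(1))
    y <- wrap_diff(p2, p1)
    out[[length(out) + 1]] <- data.frame(day = i, rel_hour = 0:23,
                                         x = x, y = y)
    daily_steps <- c(daily_steps, sum(x))
  }
  if (skipped > 0)
    message(sprintf("skipped %d day(s) missing a flanking phase", skipped))
  if (!length(out)) stop("no usable days for the PRC")
  pts <- do.call(rbind, out)
  rownames(pts) <- NULL
  prof <- vapply(0:23, function(h) mean(pts$x[pts$rel_hour == h]), numeric(1))
  structure(pts, n_days = length(daily_steps),
            mean_daily_steps = mean(daily_steps),
            mean_profile = prof,
            mean_shift = mean(pts$y[pts$rel_hour == 0]),
            class = c("prc_points", "data.frame"))
}

#' Shuffle PRC point responses across days
#'
#' Control transform: the phase-shift responses `y` are randomly permuted
#' across days while activity stays in place, destroying any real
#' activity-phase relationship — the estimated slopes should flatten.
#'
#' @param points a `prc_points` set.
#' @param seed integer seed.
#' @return a `prc_points` set with permuted `y`.
#' @export
shuffle_prc_points <- function(points, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  days <- unique(points$day)
  perm <- setNames(sample(days), days)
  ymap <- setNames(points$y[match(days, points$day)], days)
  points$y <- as.numeric(ymap[as.character(perm[as.character(points$day)])])
  points
}

#' Per-bin PRC slopes
#'
#' Ordinary least-squares slope (with intercept) of phase shift `y` on
#' activity `x` within each of the 24 relative-hour bins — the average phase
#' shift per step for activity in that bin.  Bins with fewer than 3 points
#' or no variation in `x` get a missing slope and are excluded from the
#' curve fit.
#'
#' @param points a `prc_points` set.
#' @return `data.frame(rel_hour, slope, se, n)`; slopes in h/step.
#' @export
fit_bin_slopes <- function(points) {
  res <- lapply(0:23, function(h) {
    d <- points[points$rel_hour == h, ]
    if (nrow(d) < 3 || length(unique(d$x)) < 2 || var(d$x) == 0)
      return(data.frame(rel_hour = h, slope = NA_real_, se = NA_real_,
                        n = nrow(d)))
    # closed-form OLS of y on x with intercept
    sxx <- sum((d$x - mean(d$x))^2)
    slope <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) / sxx
    resid <- d$y - mean(d$y) - slope * (d$x - mean(d$x))
    se <- sqrt(sum(resid^2) / (nrow(d) - 2) / sxx)
    data.frame(rel_hour = h, slope = slope, se = se, n = nrow(d))
  })
  out <- do.call(rbind, res)
  for (a in c("mean_daily_steps", "n_days", "mean_profile", "mean_shift"))
    attr(out, a) <- attr(points, a)
  out
}

# Asymmetric unit waveform: trough at relative hour phi, rising half-cosine
# of length tau to the peak, falling half-cosine of length 24 - tau back.
asym_wave <- function(h, phi, tau) {
  u <- wrap_hours(h - phi)
  ifelse(u < tau, -cos(pi * u / tau), cos(pi * (u - tau) / (24 - tau)))
}

#' Fit the 4-parameter asymmetric sinusoid to PRC slopes
#'
#' Least-squares fit of `m(h) = offset + A * s(h; phi, tau)` to the 24 bin
#' slopes, where `s` is a unit-amplitude 24-h periodic wave whose rising
#' half-period lasts `tau` hours (trough-to-peak time) and falling
#' half-period `24 - tau`, each half a scaled half-cosine.  The symmetric
#' sinusoid is the nested case `tau = 12`.  Fitting uses a coarse grid over
#' `(phi, tau)` with the linear parameters profiled out, followed by
#' multi-restart Nelder-Mead refinement with `tau` kept in (1, 23) by a
#' logistic transform; ties break to the lowest residual sum of squares,
#' then the lowest `tau`.
#'
#' When slope standard errors are available, bins are weighted by inverse
#' squared standard error, and bins whose standard error exceeds 3 times the
#' median are excluded: those are bins with near-degenerate activity
#' variance (typically relative hours at the edge of the waking span) whose
#' slopes are set by a handful of high-leverage days.  Set
#' `weights = FALSE` for an unweighted fit on all non-missing bins.
#'
#' @param slopes `data.frame(rel_hour, slope, se, ...)` from
#'   [fit_bin_slopes] (at least 8 usable slopes).
#' @param weights `TRUE` (default) for inverse-variance weighting with the
#'   3-times-median-SE trim, `FALSE` for unweighted, or a numeric vector of
#'   per-bin weights.
#' @param n_restarts random refinement starts beyond the grid best
#'   (default 20).
#' @param seed integer seed for the restarts.
#' @return list of class `"prc_curve"`: `offset`, `amplitude`, `phase`
#'   (trough location, relative hours), `trough_to_peak` (hours), `rss`,
#'   `rss0` (mean-only fit, same weights), `used` (logical per input bin),
#'   `fitted` (function of relative hour).
#' @export
fit_asymmetric_sinusoid <- function(slopes, weights = TRUE, n_restarts = 20,
                                    seed = 1) {
  ok <- !is.na(slopes$slope)
  w <- rep(1, nrow(slopes))
  if (is.numeric(weights)) {
    stopifnot(length(weights) == nrow(slopes))
    w <- weights
    ok <- ok & is.finite(w) & w > 0
  } else if (isTRUE(weights) && !is.null(slopes$se)) {
    se <- slopes$se
    med_se <- median(se[ok], na.rm = TRUE)
    if (is.finite(med_se) && med_se > 0) {
      ok <- ok & !is.na(se) & se <= 3 * med_se
      w[ok] <- 1 / se[ok]^2
      if (any(!is.finite(w[ok]))) w <- rep(1, nrow(slopes)) # se = 0 bins
    }
  }
  if (sum(ok) < 8) stop("need at least 8 usable slopes")
  h <- slopes$rel_hour[ok] + 0.5   # each slope sits at its bin center
  m <- slopes$slope[ok]
  wt <- sqrt(w[ok] / mean(w[ok]))
  set.seed(seed)

  lin_fit <- function(phi, tau) {
    s <- asym_wave(h, phi, tau)
    X <- cbind(1, s) * wt
    cf <- tryCatch(qr.coef(qr(X), m * wt), error = function(e) c(mean(m), 0))
    cf[is.na(cf)] <- 0
    r <- m * wt - X %*% cf
    list(offset = cf[1], A = cf[2], rss = sum(r^2))
  }
  obj <- function(par) {   # par = (phi, logit-tau)
    tau <- 1 + 22 / (1 + exp(-par[2]))
    lin_fit(par[1], tau)$rss
  }

  grid <- expand.grid(phi = seq(0, 23, by = 1), tau = seq(2, 22, by = 2))
  grid$rss <- mapply(function(p, tt) lin_fit(p, tt)$rss, grid$phi, grid$tau)
  starts <- rbind(
    as.matrix(grid[order(grid$rss)[1:5], c("phi", "tau")]),
    cbind(runif(n_restarts, 0, 24), runif(n_restarts, 2, 22)))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    v0 <- log((starts[i, 2] - 1) / (23 - starts[i, 2]))
    o <- optim(c(starts[i, 1], v0), obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
    tau <- 1 + 22 / (1 + exp(-o$par[2]))
    phi <- wrap_hours(o$par[1])
    cand <- c(rss = o$value, phi = phi, tau = tau)
    if (is.null(best) || o$value < best["rss"] - 1e-12 ||
        (abs(o$value - best["rss"]) <= 1e-12 && tau < best["tau"]))
      best <- cand
  }
  if (is.null(best) || !is.finite(best["rss"]))
    stop("asymmetric sinusoid fit failed to converge from all restarts")

  fin <- lin_fit(best["phi"], best["tau"])
  offset <- fin$offset; A <- fin$A
  phi <- best["phi"]; tau <- best["tau"]
  if (A < 0) {           # normalize: -s(h; phi, tau) = s(h; phi+tau, 24-tau)
    A <- -A
    phi <- wrap_hours(phi + tau)
    tau <- 24 - tau
  }
  mw <- sum(wt^2 * m) / sum(wt^2)
  rss0 <- sum(((m - mw) * wt)^2)
  structure(list(
    offset = unname(offset), amplitude = unname(A),
    phase = unname(phi), trough_to_peak = unname(tau),
    rss = unname(fin$rss), rss0 = rss0,
    n_bins = sum(ok), used = ok,
    mean_profile = attr(slopes, "mean_profile"),
    mean_shift = attr(slopes, "mean_shift"),
    mean_daily_steps = attr(slopes, "mean_daily_steps"),
    fitted = local({
      off <- unname(offset); Aa <- unname(A)
      ph <- unname(phi); tt <- unname(tau)
      function(hh) off + Aa * asym_wave(hh, ph, tt)
    })
  ), class = "prc_curve")
}

#' @export
print.prc_curve <- function(x, ...) {
  cat("Asymmetric sinusoid PRC fit:\n")
  cat(sprintf("  offset        %.3e h/step\n", x$offset))
  cat(sprintf("  amplitude     %.3e h/step\n", x$amplitude))
  cat(sprintf("  trough phase  %.2f relative h\n", x$phase))
  cat(sprintf("  trough-to-peak %.2f h\n", x$trough_to_peak))
  cat(sprintf("  RSS %.3e (mean-only %.3e)\n", x$rss, x$rss0))
  invisible(x)
}

#' Zero-activity daily drift of the phase
#'
#' The daily phase shift decomposes as `y = delta0 + sum_h m(h) x_h`:
#' `delta0` is the drift the clock would show on a day with no activity at
#' all (advance positive), and corresponds to the vertical position of the
#' PRC.  It is estimated as the intercept of the day-level regression of
#' the nightly shift `y` on all 24 relative-hour step totals jointly — the
#' pure zero-activity intercept, which stays unbiased when hourly step
#' totals are correlated across hours (a single-bin regression's intercept
#' does not).  Bins with no activity variation are dropped from the design.
#'
#' @param points a `prc_points` set.
#' @return list with `delta0` (hours/day), `se`, and `n_days`.
#' @export
prc_zero_activity_drift <- function(points) {
  days <- unique(points$day)
  X <- matrix(0, length(days), 24)
  y <- numeric(length(days))
  for (i in seq_along(days)) {
    d <- points[points$day == days[i], ]
    X[i, d$rel_hour + 1] <- d$x
    y[i] <- d$y[1]
  }
  keep <- apply(X, 2, function(col) var(col) > 0)
  if (length(days) < sum(keep) + 2)
    stop("too few days for the zero-activity drift regression")
  f <- lm(y ~ X[, keep, drop = FALSE])
  co <- summary(f)$coefficients
  list(delta0 = unname(coef(f)[1]), se = unname(co[1, 2]),
       n_days = length(days))
}

#' Intrinsic circadian period from the PRC vertical position
#'
#' The intrinsic period is `24 - delta0` hours, where `delta0` is the
#' zero-activity daily drift (advance positive).  When the PRC point set is
#' available, `delta0` is the day-level zero-activity regression intercept
#' ([prc_zero_activity_drift]); given only a fitted curve, it is read from
#' the curve against the mean daily activity profile by relative hour
#' (`delta0 = mean(y) - sum_h m_hat(h) xbar_h`), or, lacking a profile,
#' from the curve's vertical offset times the mean daily step total.
#'
#' @param curve a `prc_curve`.
#' @param mean_daily_steps_profile mean steps per relative hour (length-24
#'   vector); defaults to the profile recorded when the points were
#'   collected.
#' @param mean_shift mean nightly phase shift (hours/day); defaults to the
#'   recorded value, or 0.
#' @param points optionally, the `prc_points` set; if supplied the
#'   zero-activity intercept route is used.
#' @return intrinsic period in hours.
#' @export
period_from_offset <- function(curve, mean_daily_steps_profile = NULL,
                               mean_shift = NULL, points = NULL) {
  if (!is.null(points))
    return(24 - prc_zero_activity_drift(points)$delta0)
  prof <- mean_daily_steps_profile %||% curve$mean_profile
  ybar <- mean_shift %||% curve$mean_shift %||% 0
  if (!is.null(prof)) {
    stopifnot(length(prof) == 24)
    delta0 <- ybar - sum(curve$fitted(0:23 + 0.5) * prof)
  } else {
    S <- curve$mean_daily_steps
    if (is.null(S) || !is.finite(S))
      stop("no activity profile or mean_daily_steps available")
    delta0 <- ybar - curve$offset * S
  }
  24 - delta0
}

#' PRC curve characteristics
#'
#' Three scalar summaries of a fitted PRC: `sinusoidality`
#' (`1 - RSS/RSS0`, the fraction of slope variance captured by the
#' 4-parameter wave, clipped to `[0, 1]`), `amplitude` (h/step) and
#' `horizontal_shift` (the trough's relative hour).  An essentially flat
#' curve (`amplitude ~ 0`) is flagged: its horizontal shift is not
#' identifiable.
#'
#' @param curve a `prc_curve`.
#' @return list with `sinusoidality`, `amplitude`, `horizontal_shift`,
#'   `identifiable`.
#' @export
prc_characteristics <- function(curve) {
  sinu <- if (curve$rss0 > 0) 1 - curve$rss / curve$rss0 else 0
  list(sinusoidality = min(max(sinu, 0), 1),
       amplitude = curve$amplitude,
       horizontal_shift = curve$phase,
       identifiable = curve$amplitude > 1e-12)
}

#' Full PRC estimate from a phase track
#'
#' Points, per-bin slopes, asymmetric-sinusoid curve, intrinsic period and
#' curve characteristics in one call.
#'
#' @param track a `crhr_track` (estimated or ground-truth phases).
#' @param binned the `crhr_binned` series.
#' @param lag nights separating the two phase estimates (default 1).
#' @param shuffle permute responses across days first (control curve).
#' @param seed seed for the shuffle and curve-fit restarts.
#' @return an object of class `"crhr_prc"`: `points`, `slopes`, `curve`,
#'   `period_h`, `characteristics`, `lag`, `shuffled`.
#' @export
crhr_prc <- function(track, binned, lag = 1, shuffle = FALSE, seed = 1) {
  pts <- collect_prc_points(track, binned, lag = lag)
  if (shuffle) pts <- shuffle_prc_points(pts, seed = seed)
  slopes <- fit_bin_slopes(pts)
  curve <- fit_asymmetric_sinusoid(slopes, seed = seed)
  structure(list(points = pts, slopes = slopes, curve = curve,
                 period_h = period_from_offset(curve, points = pts),
                 characteristics = prc_characteristics(curve),
                 lag = lag, shuffled = shuffle),
            class = "crhr_prc")
}

#' Non-overlapping-data robustness PRC
#'
#' The same pipeline with phase changes taken across two nights
#' (`lag = 2`), so the two phase fits of each pair share no heart-rate
#' data.  Intended for comparison against the standard one-night PRC.
#'
#' @param track a `crhr_track` with at least 3 nights.
#' @param binned the `crhr_binned` series.
#' @param seed seed for the curve-fit restarts.
#' @return a `crhr_prc` (with `lag = 2`).
#' @export
prc_robustness_nonoverlap <- function(track, binned, seed = 1) {
  if (nrow(track) < 3) stop("non-overlap PRC needs at least 3 nights")
  crhr_prc(track, binned, lag = 2, seed = seed)
}

#' @export
print.crhr_prc <- function(x, ...) {
  cat(sprintf("PRC from %d day(s)%s (lag %d night%s)\n",
              attr(x$points, "n_days"),
              if (x$shuffled) " [shuffled control]" else "",
              x$lag, if (x$lag > 1) "s" else ""))
  print(x$curve)
  ch <- x$characteristics
  cat(sprintf("Intrinsic period: %.3f h; sinusoidality %.2f\n",
              x$period_h, ch$sinusoidality))
  invisible(x)
}

#' Plot a PRC
#'
#' Bin slopes with standard-error bars and the fitted asymmetric sinusoid;
#' optionally double-plotted to 36 h.
#'
#' @param x a `crhr_prc`.
#' @param double_plot extend the 24-h curve to 36 h by re-plotting the first
#'   12 bins (default `TRUE`).
#' @param ... passed to [plot()].
#' @export
plot.crhr_prc <- function(x, double_plot = TRUE, ...) {
  s <- x$slopes
  hmax <- if (double_plot) 36 else 24
  h <- s$rel_hour; sl <- s$slope; se <- s$se
  if (double_plot) {
    ext <- s$rel_hour < 12
    h <- c(h, s$rel_hour[ext] + 24); sl <- c(sl, s$slope[ext])
    se <- c(se, s$se[ext])
  }
  ylim <- range(c(sl - se, sl + se, 0), na.rm = TRUE)
  plot(h + 0.5, sl, pch = 16, xlim = c(0, hmax), ylim = ylim,
       xlab = "hours after circadian HR minimum",
       ylab = "phase shift per step (h/step)", ...)
  has_se <- !is.na(se) & se > 0
  arrows(h[has_se] + 0.5, (sl - se)[has_se], h[has_se] + 0.5,
         (sl + se)[has_se], angle = 90, code = 3, length = 0.02)
  hh <- seq(0, hmax, by = 0.1)
  lines(hh + 0.5, x$curve$fitted(wrap_hours(hh)), col = "red", lwd = 2)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Export a PRC to CSV and JSON
#'
#' @param prc a `crhr_prc`.
#' @param csv_path bin-slope table (`relative_hour, slope_h_per_step,
#'   slope_se, n_points`).
#' @param json_path curve summary (`offset, amplitude, phase,
#'   trough_to_peak, period_h, sinusoidality`).
#' @return invisibly, the paths.
#' @export
write_prc <- function(prc, csv_path, json_path) {
  s <- prc$slopes
  write.csv(data.frame(relative_hour = s$rel_hour,
                       slope_h_per_step = s$slope,
                       slope_se = s$se, n_points = s$n),
            csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    offset = prc$curve$offset, amplitude = prc$curve$amplitude,
    phase = prc$curve$phase, trough_to_peak = prc$curve$trough_to_peak,
    period_h = prc$period_h,
    sinusoidality = prc$characteristics$sinusoidality),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' Ground-truth phase track from a simulation
#'
#' Builds a track (the input the PRC estimator expects) from a simulation's
#' ground-truth ledger: one entry per interior night, with the true phase in
#' effect during the following day.  Used to validate the PRC estimator in
#' isolation from phase-estimation noise.
#'
#' @param sim a `crhr_sim`.
#' @return a `crhr_track`-shaped `data.frame` (`date`, `sleep_midpoint`,
#'   `phase_mean_h`, ...).
#' @export
track_from_ledger <- function(sim) {
  sleeps <- consolidate_sleep(sim$records$sleeps)
  dur <- as.numeric(difftime(sleeps$end, sleeps$start, units = "hours"))
  sleeps <- sleeps[dur > 2, , drop = FALSE]
  n_nights <- nrow(sleeps)
  phases <- sim$phases
  ph <- vapply(seq_len(n_nights), function(i)
    if (i + 1 <= length(phases)) phases[i + 1] else NA_real_, numeric(1))
  mid_h <- clock_hours(sleeps$midpoint)
  out <- data.frame(
    date = format(sleeps$midpoint, "%Y-%m-%d"),
    sleep_midpoint = sleeps$midpoint,
    sleep_midpoint_h = mid_h,
    phase_mean_h = ph,
    ci80_lo = ph, ci80_hi = ph,
    phase_difference_h = wrap_diff(ph, mid_h),
    n_obs = NA_integer_, flagged = FALSE)
  class(out) <- c("crhr_track", "data.frame")
  out
}
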