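# PRC estimation: point collection, per-bin slopes, asymmetric sinusoid,
# intrinsic period and characteristics.

# a minimal track with known phases on consecutive nights
toy_track <- function(phases, start = "2023-03-07 03:00:00") {
  mid <- parse_time(start) + 86400 * (seq_along(phases) - 1)
  structure(data.frame(
    date = format(mid, "%Y-%m-%d"), sleep_midpoint = mid,
    sleep_midpoint_h = crhr::wrap_hours(3), phase_mean_h = phases,
    ci80_lo = phases, ci80_hi = phases,
    phase_difference_h = 0, n_obs = NA_integer_, flagged = FALSE),
    class = c("crhr_track", "data.frame"))
}

# binned series with given steps-per-bin over the covered span
toy_binned <- function(n_days, steps_fun, start = "2023-03-07 00:00:00") {
  t0 <- parse_time(start)
  bin_start <- t0 + 300 * (0:(288 * n_days - 1))
  hod <- clock_hours(bin_start)
  out <- data.frame(bin_start = bin_start, hr = NA_real_,
                    steps_per_min = steps_fun(hod) / 5, awake = TRUE)
  attr(out, "bin_minutes") <- 5
  class(out) <- c("crhr_binned", "data.frame")
  out
}

test_that("activity is binned by hour relative to the previous night's phase", {
  # all steps at clock hour 9, previous-night phase 4 -> relative hour 5
  binned <- toy_binned(3, function(h) ifelse(floor(h) == 9, 50, 0))
  tr <- toy_track(c(4, 4, 4))
  pts <- collect_prc_points(tr, binned)
  byh <- tapply(pts$x, pts$rel_hour, sum)
  expect_true(all(byh[setdiff(names(byh), "5")] == 0))
  expect_gt(byh["5"], 0)
  # every day contributes one point to every bin, x = 0 allowed
  expect_equal(nrow(pts), 24 * length(unique(pts$day)))
  # a zero-step day yields (0, y) points in all bins
  binned0 <- toy_binned(3, function(h) 0)
  pts0 <- collect_prc_points(toy_track(c(4, 3.5, 4)), binned0)
  expect_true(all(pts0$x == 0))
  # sign convention: phase 3.5 then 3.0 is a delay of half an hour
  pts_d <- collect_prc_points(toy_track(c(3.5, 3.0, 3.5)), binned0)
  expect_equal(unique(pts_d$y[pts_d$day == 1]), -0.5)
})

test_that("relative-hour binning conserves each day's total steps", {
  set.seed(3)
  binned <- toy_binned(4, function(h) round(runif(length(h), 0, 20)))
  tr <- toy_track(c(4.2, 3.9, 4.4, 4.1))
  pts <- collect_prc_points(tr, binned)
  for (d in unique(pts$day)) {
    span <- binned$bin_start >= tr$sleep_midpoint[d] &
      binned$bin_start < tr$sleep_midpoint[d + 1]
    expect_equal(sum(pts$x[pts$day == d]),
                 sum(binned$steps_per_min[span] * 5))
  }
  # shifting every phase by 24 changes nothing
  tr24 <- tr; tr24$phase_mean_h <- tr24$phase_mean_h + 24
  pts24 <- collect_prc_points(tr24, binned)
  expect_equal(pts$x, pts24$x)
  expect_equal(pts$y, pts24$y)
})

test_that("per-bin slopes are ordinary least squares with guard rails", {
  pts <- data.frame(day = rep(1:3, each = 24), rel_hour = rep(0:23, 3),
                    x = 0, y = rep(c(0, 0.1, 0.2), each = 24))
  pts$x[pts$rel_hour == 5] <- c(0, 100, 200)
  sl <- fit_bin_slopes(structure(pts, class = c("prc_points", "data.frame")))
  expect_equal(sl$slope[sl$rel_hour == 5], 0.001)
  # bins with constant x are flagged missing
  expect_true(all(is.na(sl$slope[sl$rel_hour != 5])))
  expect_equal(sl$n, rep(3L, 24))
})

test_that("the asymmetric sinusoid recovers nested and asymmetric shapes", {
  h <- 0:23
  # pure symmetric cosine: trough at 5, amplitude 2, offset 0.5
  m <- 0.5 - 2 * cos(2 * pi * (h + 0.5 - 5) / 24)
  cv <- fit_asymmetric_sinusoid(data.frame(rel_hour = h, slope = m))
  expect_equal(cv$offset, 0.5, tolerance = 1e-4)
  expect_equal(cv$amplitude, 2, tolerance = 1e-3)
  expect_equal(cv$trough_to_peak, 12, tolerance = 0.05)
  expect_equal(wrap_hours(cv$phase), 5, tolerance = 0.05)
  # constant slopes: amplitude ~ 0, offset = the constant
  cvc <- fit_asymmetric_sinusoid(data.frame(rel_hour = h, slope = rep(3, 24)))
  expect_equal(cvc$offset, 3, tolerance = 1e-6)
  expect_lt(cvc$amplitude, 1e-6)
  # asymmetric wave with trough-to-peak 9 plus 5% noise
  set.seed(14)
  truth <- list(offset = 1, A = 2, phi = 7, tau = 9)
  s <- crhr:::asym_wave(h + 0.5, truth$phi, truth$tau)
  m2 <- truth$offset + truth$A * s + rnorm(24, 0, 0.1)
  cv2 <- fit_asymmetric_sinusoid(data.frame(rel_hour = h, slope = m2),
                                 n_restarts = 50)
  expect_equal(cv2$offset, truth$offset, tolerance = 0.15)
  expect_equal(cv2$amplitude, truth$A, tolerance = 0.2)
  expect_equal(cv2$trough_to_peak, truth$tau, tolerance = 1.5)
  expect_lt(abs(wrap_diff(cv2$phase, truth$phi)), 1)
  # too few usable bins
  expect_error(fit_asymmetric_sinusoid(
    data.frame(rel_hour = 0:6, slope = rnorm(7))), "at least 8")
})

test_that("period derives from the zero-activity drift, 24 h when flat", {
  h <- 0:23
  cv <- fit_asymmetric_sinusoid(data.frame(rel_hour = h, slope = rep(0, 24)))
  cv$mean_profile <- rep(400, 24)
  cv$mean_shift <- 0
  expect_equal(period_from_offset(cv), 24)
  # a -0.03 h/day zero-activity drift means a 24.03-h intrinsic period
  cv$mean_shift <- -0.03
  expect_equal(period_from_offset(cv), 24.03)
  # curve-offset fallback: offset * daily steps balances the drift
  cv2 <- fit_asymmetric_sinusoid(data.frame(rel_hour = h,
                                            slope = rep(3e-6, 24)))
  cv2$mean_profile <- NULL; cv2$mean_shift <- NULL
  cv2$mean_daily_steps <- 10000
  expect_equal(period_from_offset(cv2), 24 + 0.03, tolerance = 1e-6)
})

test_that("characteristics report sinusoidality, amplitude and shift", {
  h <- 0:23
  m <- 1 - 2 * cos(2 * pi * (h + 0.5 - 5) / 24)
  cv <- fit_asymmetric_sinusoid(data.frame(rel_hour = h, slope = m))
  ch <- prc_characteristics(cv)
  expect_equal(ch$sinusoidality, 1, tolerance = 1e-6)
  expect_true(ch$identifiable)
  set.seed(4)
  sinus <- replicate(20, {
    cvn <- fit_asymmetric_sinusoid(
      data.frame(rel_hour = h, slope = rnorm(24)), n_restarts = 5, seed = 1)
    prc_characteristics(cvn)$sinusoidality
  })
  # white-noise slopes: low sinusoidality on average (a 4-parameter wave can
  # always soak up some variance, so not exactly zero)
  expect_lt(mean(sinus), 0.5)
  cv0 <- fit_asymmetric_sinusoid(data.frame(rel_hour = h, slope = rep(1, 24)))
  ch0 <- prc_characteristics(cv0)
  expect_equal(ch0$amplitude, 0, tolerance = 1e-6)
  expect_false(ch0$identifiable)
})

test_that("shuffling responses across days flattens the slopes", {
  set.seed(9)
  binned <- toy_binned(30, function(h) rpois(length(h), 10))
  ph <- wrap_hours(3.3 + cumsum(rnorm(30, 0, 0.3)))
  tr <- toy_track(ph)
  pts <- collect_prc_points(tr, binned)
  sh <- shuffle_prc_points(pts, seed = 2)
  # y values are a permutation across days, x untouched
  expect_equal(sort(unique(sh$y)), sort(unique(pts$y)))
  expect_equal(sh$x, pts$x)
  expect_false(identical(sh$y, pts$y))
})

test_that("the non-overlap variant requires 3 nights and uses 2-night shifts", {
  binned <- toy_binned(2, function(h) 5)
  expect_error(prc_robustness_nonoverlap(toy_track(c(4, 4)), binned),
               "3 nights")
  set.seed(10)
  binned5 <- toy_binned(6, function(h) rpois(length(h), 8))
  ph <- c(4, 4.5, 4.2, 4.8, 4.4, 4.6)
  pts2 <- collect_prc_points(toy_track(ph), binned5, lag = 2)
  # y spans two nights
  expect_equal(unique(pts2$y[pts2$day == 1]), wrap_diff(ph[3], ph[1]))
})

test_that("prc export writes the documented CSV and JSON schema", {
  set.seed(11)
  binned <- toy_binned(40, function(h) rpois(length(h), 12))
  ph <- wrap_hours(3.3 + cumsum(rnorm(40, 0, 0.4)))
  prc <- crhr_prc(toy_track(ph), binned)
  csvp <- tempfile(fileext = ".csv"); jsonp <- tempfile(fileext = ".json")
  write_prc(prc, csvp, jsonp)
  tab <- read.csv(csvp)
  expect_named(tab, c("relative_hour", "slope_h_per_step", "slope_se",
                      "n_points"))
  expect_equal(nrow(tab), 24)
  js <- jsonlite::read_json(jsonp)
  expect_setequal(names(js), c("offset", "amplitude", "phase",
                               "trough_to_peak", "period_h", "sinusoidality"))
})
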