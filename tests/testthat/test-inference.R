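# Posterior construction, per-window fits, sequential phase tracking and
# phase-difference analytics.

test_that("log_posterior applies the box and the circular phase prior", {
  p <- paper_params()
  obs <- random_gap_series(30, p, seed = 2)
  prior <- crhr_prior()
  # flat prior equals the likelihood
  expect_equal(log_posterior(p, obs, prior), ar1_loglik(p, obs))
  # outside the box
  out <- unclass(p); out["a"] <- 150
  expect_identical(log_posterior(out, obs, prior), -Inf)
  # circular prior: c = 5 and c = 29 are the same hour
  prior_c <- crhr_prior(c_prior = c(4, 1))
  p5 <- unclass(p); p5["c"] <- 5
  p29 <- unclass(p); p29["c"] <- 29
  expect_equal(log_posterior(p5, obs, prior_c), log_posterior(p29, obs, prior_c))
  # and is a proper penalty relative to the flat prior
  expect_equal(log_posterior(p5, obs, prior_c) - log_posterior(p5, obs, prior),
               dnorm(1, 0, 1, log = TRUE))
})

test_that("prior specification validates bounds", {
  expect_error(crhr_prior(bounds = list(zz = c(0, 1))), "unknown")
  expect_error(crhr_prior(bounds = list(a = c(5, 2))), "ordered")
  expect_error(crhr_prior(c_prior = c(3, 0)), "sd")
})

test_that("fit_window summarizes the posterior with 80% intervals", {
  qw <- quick_window(seed = 101)
  f <- fit_window(qw$window, n_total_samples = 15000, seed = 3)
  s <- f$summary
  expect_setequal(s$param, c("a", "b", "c", "d", "sigma", "k"))
  # point estimate inside its interval (circular for c)
  for (j in seq_len(6)) {
    if (s$param[j] == "c") {
      expect_true(arc_covers(s$lo80[j], s$hi80[j], s$mean[j]))
    } else {
      expect_true(s$lo80[j] <= s$mean[j] && s$mean[j] <= s$hi80[j])
    }
  }
  # activity effect and noise scale are well identified in one window
  expect_lt(abs(s$mean[s$param == "d"] - 0.32), 0.1)
  expect_lt(abs(s$mean[s$param == "sigma"] - 6.9), 1.5)
  # S3 surface
  expect_named(coef(f), c("a", "b", "c", "d", "sigma", "k"))
  expect_length(predict(f), nrow(qw$window$observations))
  expect_equal(residuals(f), qw$window$observations$hr - fitted(f))
  expect_s3_class(summary(f), "summary.crhr_fit")
  expect_equal(attr(logLik(f), "df"), 6)
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(qw$window$observations), 2))
  # audit dump: one row per draw
  path <- tempfile(fileext = ".csv")
  write_samples(f, path)
  cloud <- read.csv(path)
  expect_named(cloud, c("a", "b", "c", "d", "sigma", "k"))
  expect_equal(nrow(cloud), f$n_samples)
})

test_that("with b = 0 the phase is unidentifiable and the interval says so", {
  width_for <- function(seed, params) {
    qw <- quick_window(seed = seed, params = params)
    f <- fit_window(qw$window, n_total_samples = 20000, seed = 4)
    s <- f$summary
    wrap_hours(s$hi80[s$param == "c"] - s$lo80[s$param == "c"])
  }
  flat <- crhr_params(73.5, 1e-3, 3.3, 0.32, 6.9, 0.93)
  w0 <- vapply(55:58, width_for, numeric(1), params = flat)
  # without a rhythm the 80% interval spans a large part of the circle
  # (its exact width fluctuates: the flat amplitude prior lets the fit chase
  # whatever spurious rhythm the noise realization contains)
  expect_gt(median(w0), 6)
})

test_that("phase difference follows the advance-positive sign convention", {
  # sleep centered at 10:29 with HR minimum at 04:00 means the clock is
  # advanced relative to the sleep-wake cycle
  expect_equal(wrap_diff(4.0, 10 + 29 / 60), -6.483, tolerance = 1e-3)
  expect_equal(wrap_diff(3.5, 3.0), 0.5)
  expect_equal(wrap_diff(23.5, 0.5), -1)
})

test_that("tracking with an essentially flat phase prior matches independent
           fits", {
  qw <- quick_window(seed = 7, params = paper_params(b = 6, k = 0.9339^5),
                     n_days = 4)
  prep <- qw$prep
  tr_wide <- track_phases(prep$windows, n_total_samples = 8000, seed = 11,
                          prior_sd_hours = 1e5)
  ind <- vapply(seq_along(prep$windows), function(i)
    unname(coef(fit_window(prep$windows[[i]], n_total_samples = 8000,
                           seed = (11 + i) %% .Machine$integer.max))["c"]),
    numeric(1))
  # same seeds, and a prior so wide it changes the density by a near-constant:
  # estimates agree to within Monte Carlo noise of the same chains
  expect_equal(tr_wide$phase_mean_h, ind, tolerance = 1e-6)
})

test_that("sequential tracking tightens the phase against a constant schedule", {
  pk <- paper_params(b = 6, k = 0.9339^5)
  sim <- crhr_simulate(sim_config(params = pk, n_days = 8, seed = 19))
  prep <- crhr_preprocess(sim$records)
  tr <- track_phases(prep$windows, n_total_samples = 12000, seed = 21)
  expect_equal(nrow(tr), length(prep$windows))
  expect_false(any(tr$flagged))
  # the tracked estimates stay within ~1.5 h of the pinned truth on average
  err <- abs(wrap_diff(tr$phase_mean_h, 3.3))
  expect_lt(median(err), 1.5)
  # intervals are capped near the 1-h sequential prior width
  widths <- wrap_hours(tr$ci80_hi - tr$ci80_lo)[-1]
  expect_lt(median(widths), 3.5)
  # phase differences are computed against the sleep midpoint
  expect_equal(tr$phase_difference_h,
               wrap_diff(tr$phase_mean_h, tr$sleep_midpoint_h))
  # CSV export round-trips
  path <- tempfile(fileext = ".csv")
  write_phase_track(tr, path)
  back <- read.csv(path)
  expect_equal(back$phase_mean_h, tr$phase_mean_h, tolerance = 1e-6)
})

test_that("credible intervals are calibrated when truth is drawn from the
           prior", {
  set.seed(99)
  n <- 50
  cov6 <- matrix(NA, n, 6)
  for (s in 1:n) {
    tr <- c(a = runif(1, 55, 100), b = runif(1, 0, 12), c = runif(1, 0, 24),
            d = runif(1, 0, 1), sigma = runif(1, 2, 15),
            k = runif(1, 0.1, 0.97))
    p <- crhr_params(tr[1], tr[2], tr[3], tr[4], tr[5], tr[6])
    qw <- quick_window(seed = 7000 + s, params = p,
                       clock = true_clock(phase0 = tr["c"]))
    f <- fit_window(qw$window, n_total_samples = 20000, seed = s)
    sm <- f$summary
    for (j in 1:6) {
      cov6[s, j] <- if (sm$param[j] == "c")
        arc_covers(sm$lo80[j], sm$hi80[j], tr["c"])
      else sm$lo80[j] <= tr[sm$param[j]] & tr[sm$param[j]] <= sm$hi80[j]
    }
  }
  rates <- colMeans(cov6)
  # 80% nominal; allow Monte Carlo slack at n = 50
  expect_true(all(rates > 0.62), info = paste(round(rates, 2), collapse = " "))
  expect_true(all(rates < 0.95), info = paste(round(rates, 2), collapse = " "))
})

test_that("pacf matches the known AR(1) signature and stats::pacf", {
  set.seed(12)
  n <- 1000; phi <- 0.6
  x <- as.numeric(arima.sim(list(ar = phi), n))
  p <- pacf_with_bounds(x, max_lag = 10)
  expect_equal(p$pacf[1], phi, tolerance = 0.1)
  expect_true(all(abs(p$pacf[3:10]) < 3 / sqrt(n) * 2))
  # lag-1 PACF is exactly the lag-1 autocorrelation
  r1 <- as.numeric(acf(x, lag.max = 1, plot = FALSE)$acf)[2]
  expect_equal(p$pacf[1], r1)
  # independent oracle: stats::pacf
  expect_equal(p$pacf, as.numeric(pacf(x, lag.max = 10, plot = FALSE)$acf),
               tolerance = 1e-8)
  # white-noise series stays inside the 95% bounds at most lags
  set.seed(13)
  w <- rnorm(1000)
  pw <- pacf_with_bounds(w, max_lag = 15)
  expect_gte(mean(pw$pacf < pw$upper & pw$pacf > pw$lower), 12 / 15)
  expect_equal(pw$upper[1], qnorm(0.975) / sqrt(1000))
  # degenerate input
  expect_error(pacf_with_bounds(rep(1, 100)), "constant")
  expect_error(pacf_with_bounds(rnorm(10), max_lag = 15), "short")
})
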