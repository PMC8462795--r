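# Ground-truth simulator: schedules, clock dynamics, record generation.

test_that("a regular schedule yields the configured nightly sleeps", {
  cfg <- sim_config(n_days = 10, seed = 3, jitter_minutes = 0)
  sch <- simulate_schedule(cfg)
  expect_equal(nrow(sch$sleeps), 9)
  dur <- as.numeric(difftime(sch$sleeps$end, sch$sleeps$start, units = "hours"))
  expect_equal(dur, rep(8, 9))
  expect_true(all(sch$bins$steps[!sch$bins$awake] == 0))
})

test_that("a shift transition displaces the activity pattern", {
  cfg <- sim_config(n_days = 10, seed = 3, shift_day = 5, shift_hours = 7,
                    jitter_minutes = 0)
  sch <- simulate_schedule(cfg)
  starts <- clock_hours(sch$sleeps$start)
  expect_equal(unname(starts[1]), 23)
  expect_equal(unname(starts[8]), 6)   # 23 + 7 (mod 24)
})

test_that("nap days exercise the 2-h rule without splitting days downstream", {
  cfg <- sim_config(n_days = 5, seed = 11, nap_prob = 1, nap_minutes = 90)
  sim <- crhr_simulate(cfg)
  dur_h <- as.numeric(difftime(sim$records$sleeps$end,
                               sim$records$sleeps$start, units = "hours"))
  expect_true(any(dur_h < 2))
  prep <- crhr_preprocess(sim$records)
  expect_equal(length(prep$windows), 4)
})

test_that("config validation rejects impossible schedules", {
  expect_error(sim_config(n_days = 1, seed = 1), "n_days")
  expect_error(sim_config(n_days = 5, seed = 1, bed_hour = 23, wake_hour = 0.5),
               "longer than 2")
  expect_error(sim_config(n_days = 5), "seed")
})

test_that("the clock map has the documented limits", {
  cfg <- sim_config(n_days = 6, seed = 4)
  sch <- simulate_schedule(cfg)
  # no PRC, 24-h period: constant phase
  ph <- evolve_clock(true_clock(period = 24), sch$bins, sch$origin, 6)
  expect_equal(ph, rep(3.3, 6))
  # no PRC, 24.2-h period: pure drift of 0.2 h/day
  ph2 <- evolve_clock(true_clock(period = 24.2), sch$bins, sch$origin, 6)
  expect_equal(diff(ph2), rep(-0.2, 5))
  expect_equal(wrap_diff(ph2[6], ph2[1]), -1)
})

test_that("a sinusoidal PRC entrains the clock to a stable phase", {
  ck <- true_clock(period = 24, prc = prc_template(0, 2e-4, 16), phase0 = 6)
  cfg <- sim_config(n_days = 60, seed = 8, clock = ck)
  sim <- crhr_simulate(cfg)
  tail_ph <- sim$phases[45:60]
  # converged: late phases hover around a fixed point
  dev <- abs(wrap_diff(tail_ph, circular_mean_hours(tail_ph)))
  expect_lt(max(dev), 1.5)
  # and the fixed point is an attractor: different start, same end
  ck2 <- true_clock(period = 24, prc = prc_template(0, 2e-4, 16), phase0 = 2)
  sim2 <- crhr_simulate(sim_config(n_days = 60, seed = 8, clock = ck2))
  expect_lt(abs(wrap_diff(mean(sim2$phases[50:60]), mean(sim$phases[50:60]))),
            1)
})

test_that("noise-free records reduce to the exact cosinor curve", {
  p <- crhr_params(73.5, 4, 3.3, 0, 1e-9, 0)
  sim <- crhr_simulate(sim_config(params = p, n_days = 3, seed = 2,
                                  emit_sleep_hr = FALSE))
  rec <- sim$records
  t <- as.numeric(difftime(rec$hr$time, sim$schedule$origin, units = "hours"))
  expect_equal(rec$hr$bpm, round(mean_hr(p, t, 0), 1), tolerance = 1e-6)
})

test_that("emitted residuals have the stationary AR(1) moments", {
  p <- paper_params()
  sim <- crhr_simulate(sim_config(params = p, n_days = 40, seed = 6,
                                  emit_sleep_hr = FALSE))
  rec <- sim$records
  t <- as.numeric(difftime(rec$hr$time, sim$schedule$origin, units = "hours"))
  day <- pmin(floor(t / 24) + 1, 40)
  steps_rate <- rec$steps$steps[match(rec$hr$time, rec$steps$time)] / 5
  mu <- 73.5 - 4 * cos(pi / 12 * (t - sim$phases[day])) + 0.32 * steps_rate
  r <- rec$hr$bpm - mu
  vstat <- 6.9^2 / (1 - 0.93^2)
  expect_equal(var(r), vstat, tolerance = 0.15 * vstat)
  adj <- which(diff(round(t * 12)) == 1)
  lag1 <- cor(r[adj], r[adj + 1])
  expect_equal(lag1, 0.93, tolerance = 0.03)
})

test_that("simulation is bit-reproducible from its seed", {
  s1 <- crhr_simulate(sim_config(n_days = 4, seed = 99))
  s2 <- crhr_simulate(sim_config(n_days = 4, seed = 99))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$ledger, s2$ledger)
  s3 <- crhr_simulate(sim_config(n_days = 4, seed = 100))
  expect_false(identical(s1$records$hr$bpm, s3$records$hr$bpm))
})

test_that("no awake bin overlaps a sleep interval in emitted data", {
  sim <- crhr_simulate(sim_config(n_days = 6, seed = 12, nap_prob = 0.5))
  b <- sim$schedule$bins
  sl <- sim$records$sleeps
  for (i in seq_len(nrow(sl))) {
    inside <- b$bin_start < sl$end[i] & b$bin_start + 300 > sl$start[i]
    expect_false(any(b$awake[inside]))
  }
})

test_that("refitting phases on ledger data recovers the recorded truth", {
  # fix all parameters at truth, free only the phase, grid-maximize per window
  pk <- paper_params(b = 6, k = 0.9339^5)
  sim <- crhr_simulate(sim_config(params = pk, n_days = 6, seed = 44))
  prep <- crhr_preprocess(sim$records)
  errs <- vapply(seq_along(prep$windows), function(i) {
    w <- prep$windows[[i]]
    cgrid <- seq(0, 23.9, by = 0.1)
    ll <- vapply(cgrid, function(cc) {
      q <- unclass(pk); q["c"] <- cc
      ar1_loglik(q, w$observations)
    }, numeric(1))
    abs(wrap_diff(cgrid[which.max(ll)], sim$phases[i + 1]))
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("the generic CSV round-trips through the reader", {
  sim <- crhr_simulate(sim_config(n_days = 3, seed = 21))
  d <- tempfile(); dir.create(d)
  write_generic_csv(sim, d)
  rec <- read_device_export(file.path(d, "streams.csv"), "generic")
  expect_equal(nrow(rec$hr), nrow(sim$records$hr))
  expect_equal(rec$hr$bpm, sim$records$hr$bpm[order(sim$records$hr$time)])
  expect_equal(nrow(rec$sleeps), nrow(sim$records$sleeps))
  led <- read.csv(file.path(d, "ledger.csv"))
  expect_equal(led$true_phase_h, sim$ledger$true_phase_h)
})
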