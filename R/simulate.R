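# Synthetic wearable streams with known ground truth: model-exact HR with
# AR(1) noise, structured activity and sleep schedules (shift transitions,
# naps, charging gaps), and an optional dynamic clock with a known intrinsic
# period and phase-response curve.  Every other module gets its recovery
# oracle from here.

#' Ground-truth circadian clock for simulation
#'
#' A fixed clock keeps a constant phase.  A dynamic clock advances each
#' midnight by `(24 - intrinsic_period)` hours plus the summed effect of the
#' day's activity through its phase-response curve:
#' `phase_{n+1} = wrap(phase_n + (24 - period) + sum_bins prc(rel_hour) * steps)`.
#' Positive shifts are phase advances, negative are delays.
#'
#' @param period intrinsic period in hours (in `[22, 26]`).
#' @param prc `NULL` for a fixed clock, or a function mapping relative hour
#'   (hours after the circadian HR minimum, in `[0, 24)`) to phase shift per
#'   step (hours/step).
#' @param phase0 initial phase (clock hour of the HR minimum), default 3.3.
#' @return an object of class `"true_clock"`.
#' @export
true_clock <- function(period = 24, prc = NULL, phase0 = 3.3) {
  if (period < 22 || period > 26) stop("period must lie in [22, 26] hours")
  if (!is.null(prc) && !is.function(prc)) stop("prc must be NULL or a function")
  structure(list(period = period, prc = prc, phase0 = wrap_hours(phase0)),
            class = "true_clock")
}

#' Sinusoidal phase-response curve template
#'
#' `prc(h) = dc + amplitude * cos(2*pi*(h - peak_hour)/24)`: maximal advance
#' at relative hour `peak_hour`, maximal delay 12 h away, plus a constant
#' (DC) component.  The DC component is what a non-24-h intrinsic period
#' must be balanced against under entrainment, and is what the PRC's
#' vertical offset recovers.
#'
#' @param dc constant shift per step (h/step).
#' @param amplitude oscillating amplitude (h/step).
#' @param peak_hour relative hour of maximal advance.
#' @return a function of relative hour.
#' @export
prc_template <- function(dc = 0, amplitude = 0, peak_hour = 6) {
  force(dc); force(amplitude); force(peak_hour)
  function(h) dc + amplitude * cos(2 * pi * (h - peak_hour) / 24)
}

#' Simulation configuration
#'
#' Defaults reproduce the population-typical data regime: the six model
#' parameters at their population central values (`a = 73.5` bpm,
#' `b = 4.0` bpm, `c = 3.3` h, `d = 0.32` bpm/(steps/min), `sigma = 6.9`
#' bpm, `k = 0.93` per 5-min bin), a 23:00-07:00 sleep schedule, lognormal
#' waking activity with commute peaks and occasional exercise bouts
#' (roughly 9-10k steps/day spanning 0-100+ steps/min), and a fixed 24-h
#' clock.
#'
#' @param params true model parameters ([crhr_params]).
#' @param n_days number of simulated civil days (`>= 2`).
#' @param bed_hour,wake_hour habitual sleep schedule, clock hours
#'   (`bed_hour` may exceed 24 to mean after midnight).
#' @param shift_day,shift_hours from night `shift_day` onward the schedule
#'   moves `shift_hours` later (`NA` for no shift).
#' @param jitter_minutes s.d. of night-to-night Gaussian jitter on bed and
#'   wake times (default 20).
#' @param nap_prob probability of a nap each day; `nap_hour`,
#'   `nap_minutes` its timing and length.
#' @param exercise_prob expected number of 30-min brisk-activity episodes
#'   per day; episodes occur independently across clock hours.
#' @param charging_gaps optional `data.frame(day, start_hour, hours)`: HR
#'   and step records are removed in those spans.
#' @param emit_sleep_hr emit HR during sleep (basal minus a fixed 8-bpm dip,
#'   not model-governed) so preprocessing can be shown to discard it.
#' @param clock a [true_clock].
#' @param start_date first civil day (date string).
#' @param seed integer seed; mandatory.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(params = crhr_params(73.5, 4.0, 3.3, 0.32, 6.9, 0.93),
                       n_days = 14, bed_hour = 23, wake_hour = 7,
                       shift_day = NA, shift_hours = 0, jitter_minutes = 20,
                       nap_prob = 0, nap_hour = 14, nap_minutes = 90,
                       exercise_prob = 0.7, charging_gaps = NULL,
                       emit_sleep_hr = TRUE, clock = true_clock(),
                       start_date = "2023-03-06", seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  if (n_days < 2) stop("n_days must be >= 2 (fit windows need two days)")
  sleep_len <- (24 - bed_hour %% 24 + wake_hour) %% 24
  if (sleep_len <= 2) stop("schedule must yield sleeps longer than 2 h")
  structure(list(params = params, n_days = as.integer(n_days),
                 bed_hour = bed_hour, wake_hour = wake_hour,
                 shift_day = shift_day, shift_hours = shift_hours,
                 jitter_minutes = jitter_minutes, nap_prob = nap_prob,
                 nap_hour = nap_hour, nap_minutes = nap_minutes,
                 exercise_prob = exercise_prob,
                 charging_gaps = charging_gaps,
                 emit_sleep_hr = emit_sleep_hr, clock = clock,
                 start_date = start_date, seed = as.integer(seed)),
            class = "sim_config")
}

# Waking activity model: lognormal steps/min per 5-min bin scaled by a
# time-of-day profile with morning/evening commute peaks, plus an optional
# 30-min exercise bout.  Spans the 0-100+ steps/min regime.
activity_profile_multiplier <- function(hour_of_day) {
  1 + 1.6 * exp(-((hour_of_day - 8.5)^2) / 0.8) +
    1.6 * exp(-((hour_of_day - 17.5)^2) / 1.2)
}

#' Simulate a sleep/activity schedule
#'
#' Generates the full 5-minute grid for the configured days: step counts per
#' bin (zero during sleep), sleep intervals (nightly sleeps plus naps), and
#' the awake flag.  Reproducible from the config seed.
#'
#' @param config a [sim_config].
#' @return list with `bins` (`data.frame(bin_start, steps, awake)`),
#'   `sleeps` (`data.frame(start, end)`, naps included), `origin` (POSIXct
#'   midnight of day 1).
#' @export
simulate_schedule <- function(config) {
  set.seed(config$seed)
  origin <- parse_time(paste(config$start_date, "00:00:00"))
  n_bins <- config$n_days * 288L
  bin_start <- origin + (seq_len(n_bins) - 1L) * 300

  nights <- seq_len(config$n_days - 1L)
  bed <- rep(config$bed_hour, length(nights))
  wake <- rep(config$wake_hour, length(nights))
  if (!is.na(config$shift_day)) {
    late <- nights >= config$shift_day
    bed[late] <- bed[late] + config$shift_hours
    wake[late] <- wake[late] + config$shift_hours
  }
  jit <- config$jitter_minutes / 60
  bed <- bed + rnorm(length(nights), 0, jit)
  wake <- wake + rnorm(length(nights), 0, jit)
  s_start <- as.numeric(origin) + (nights - 1) * 86400 + bed * 3600
  s_end <- as.numeric(origin) + nights * 86400 + (wake %% 24) * 3600
  if (any(s_end <= s_start)) stop("schedule yields non-positive sleep")
  if (any(s_start[-1] < s_end[-length(s_end)]))
    stop("schedule yields overlapping sleeps")
  sleeps <- data.frame(
    start = as.POSIXct(s_start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(s_end, origin = "1970-01-01", tz = "UTC"))

  # naps: short device-labelled sleeps that must not split days downstream
  if (config$nap_prob > 0) {
    for (day in seq_len(config$n_days)) {
      if (runif(1) < config$nap_prob) {
        ns <- as.numeric(origin) + (day - 1) * 86400 + config$nap_hour * 3600
        ne <- ns + config$nap_minutes * 60
        if (!any(ns < as.numeric(sleeps$end) & ne > as.numeric(sleeps$start)))
          sleeps <- rbind(sleeps, data.frame(
            start = as.POSIXct(ns, origin = "1970-01-01", tz = "UTC"),
            end = as.POSIXct(ne, origin = "1970-01-01", tz = "UTC")))
      }
    }
    sleeps <- sleeps[order(sleeps$start), ]
  }

  asleep <- rep(FALSE, n_bins)
  bs <- as.numeric(bin_start)
  for (i in seq_len(nrow(sleeps))) {
    asleep[bs < as.numeric(sleeps$end[i]) &
             bs + 300 > as.numeric(sleeps$start[i])] <- TRUE
  }
  # record starts at the first wake and ends at the last bedtime so boundary
  # days are clean
  first_wake <- as.numeric(origin) + (config$wake_hour %% 24) * 3600
  keep <- bs >= first_wake
  bin_start <- bin_start[keep]; asleep <- asleep[keep]; bs <- bs[keep]
  n_bins <- length(bin_start)

  hod <- ((bs - as.numeric(origin)) / 3600) %% 24
  steps <- numeric(n_bins)
  awake_idx <- which(!asleep)
  mult <- activity_profile_multiplier(hod[awake_idx])
  rate <- rlnorm(length(awake_idx), meanlog = log(4), sdlog = 1.0) * mult
  steps[awake_idx] <- round(pmin(rate, 160) * 5)

  # brisk-activity episodes: each fully-awake clock hour independently has a
  # small probability of one 30-min 60-120 steps/min episode, kept inside
  # that hour.  Independence across hours means hourly step totals carry no
  # built-in cross-hour covariance (which would bias downstream per-bin
  # regressions); exercise_prob is the expected number of episodes per day.
  if (config$exercise_prob > 0) {
    day_of <- floor((bs - as.numeric(origin)) / 86400) + 1
    hour_id <- day_of * 24 + floor(hod)
    awake_hours <- tapply(!asleep, hour_id, all)
    eligible <- as.numeric(names(awake_hours))[awake_hours]
    n_wake_h <- max(1, length(eligible) / config$n_days)
    p_hour <- min(1, config$exercise_prob / n_wake_h)
    hit <- eligible[runif(length(eligible)) < p_hour]
    for (hh in hit) {
      cand <- which(hour_id == hh)
      if (length(cand) >= 12) {
        j0 <- sample(1:7, 1)
        sel <- cand[j0:(j0 + 5)]
        steps[sel] <- steps[sel] + round(runif(6, 60, 120) * 5)
      }
    }
  }

  list(bins = data.frame(bin_start = bin_start, steps = steps,
                         awake = !asleep),
       sleeps = sleeps, origin = origin)
}

#' Evolve the ground-truth clock over a simulated record
#'
#' Iterates the daily phase map: each civil day's activity, binned by hour
#' relative to that day's phase, shifts the next day's phase through the
#' clock's PRC, on top of the free-running drift `24 - period`.
#'
#' @param clock a [true_clock].
#' @param bins `data.frame(bin_start, steps)` at 5-min resolution.
#' @param origin POSIXct midnight of day 1.
#' @param n_days number of civil days.
#' @return numeric vector of daily phases (hours, wrapped), one per day.
#' @export
evolve_clock <- function(clock, bins, origin, n_days) {
  phases <- numeric(n_days)
  phases[1] <- clock$phase0
  if (n_days < 2) return(phases)
  bs <- as.numeric(bins$bin_start)
  day_of <- floor((bs - as.numeric(origin)) / 86400) + 1
  hod <- ((bs - as.numeric(origin)) / 3600) %% 24
  for (n in seq_len(n_days - 1)) {
    delta <- 24 - clock$period
    if (!is.null(clock$prc)) {
      sel <- day_of == n & bins$steps > 0
      if (any(sel)) {
        rel <- wrap_hours(hod[sel] - phases[n])
        delta <- delta + sum(clock$prc(rel) * bins$steps[sel])
      }
    }
    phases[n + 1] <- wrap_hours(phases[n] + delta)
  }
  phases
}

#' Simulate wearable records from the model
#'
#' Emits heart-rate and step records on the 5-minute grid: waking HR is the
#' model mean (with `c` set to that day's true phase) plus a stationary
#' AR(1) residual propagated exactly across gaps; sleep HR, when emitted, is
#' basal minus a fixed 8-bpm dip (not model-governed) purely so that
#' preprocessing can be shown to discard it.  Charging gaps remove both HR
#' and step records.
#'
#' @param config a [sim_config].
#' @return list of class `"crhr_sim"`: `records` (a `crhr_records`),
#'   `ledger` (`data.frame(date, true_phase_h, a, b, c, d, sigma, k)`),
#'   `schedule`, `phases`, `config`.
#' @export
crhr_simulate <- function(config) {
  sched <- simulate_schedule(config)
  bins <- sched$bins
  phases <- evolve_clock(config$clock, bins, sched$origin, config$n_days)

  p <- as_param_vector(config$params)
  bs <- as.numeric(bins$bin_start)
  day_of <- pmin(pmax(floor((bs - as.numeric(sched$origin)) / 86400) + 1, 1),
                 config$n_days)
  t_hours <- (bs - as.numeric(sched$origin)) / 3600

  # drop charging-gap bins entirely
  emit <- rep(TRUE, nrow(bins))
  if (!is.null(config$charging_gaps)) {
    cg <- config$charging_gaps
    for (i in seq_len(nrow(cg))) {
      g0 <- (cg$day[i] - 1) * 24 + cg$start_hour[i]
      emit[t_hours >= g0 & t_hours < g0 + cg$hours[i]] <- FALSE
    }
  }

  awake_emit <- which(bins$awake & emit)
  n <- length(awake_emit)
  r <- numeric(n)
  vstat <- p[5]^2 / (1 - p[6]^2)
  r[1] <- rnorm(1, 0, sqrt(vstat))
  if (n > 1) {
    g <- round(diff(bs[awake_emit]) / 300)
    kg <- p[6]^g
    innov <- rnorm(n - 1, 0, sqrt(vstat * (1 - kg^2)))
    for (i in 2:n) r[i] <- kg[i - 1] * r[i - 1] + innov[i - 1]
  }
  mu <- p[1] -
    p[2] * cos(pi / 12 * (t_hours[awake_emit] - phases[day_of[awake_emit]])) +
    p[4] * bins$steps[awake_emit] / 5
  hr_awake <- mu + r

  hr_time <- bins$bin_start[awake_emit]
  hr_val <- hr_awake
  if (config$emit_sleep_hr) {
    sleep_emit <- which(!bins$awake & emit)
    if (length(sleep_emit)) {
      hr_sleep <- p[1] - 8 + rnorm(length(sleep_emit), 0, 3)
      hr_time <- c(hr_time, bins$bin_start[sleep_emit])
      hr_val <- c(hr_val, hr_sleep)
      o <- order(hr_time)
      hr_time <- hr_time[o]; hr_val <- hr_val[o]
    }
  }

  step_idx <- which(bins$awake & emit)
  records <- structure(list(
    hr = data.frame(time = hr_time, bpm = round(hr_val, 1)),
    steps = data.frame(time = bins$bin_start[step_idx],
                       steps = bins$steps[step_idx]),
    sleeps = sched$sleeps
  ), dialect = "generic", n_skipped = 0L, class = "crhr_records")

  ledger <- data.frame(
    date = format(sched$origin + (seq_len(config$n_days) - 1) * 86400,
                  "%Y-%m-%d"),
    true_phase_h = phases,
    a = p[1], b = p[2], c = p[3], d = p[4], sigma = p[5], k = p[6])

  structure(list(records = records, ledger = ledger, schedule = sched,
                 phases = phases, config = config),
            class = "crhr_sim")
}

#' @export
print.crhr_sim <- function(x, ...) {
  cat(sprintf("Simulated recording: %d days, %d HR records, %d sleep intervals\n",
              x$config$n_days, nrow(x$records$hr), nrow(x$records$sleeps)))
  cat(sprintf("Clock: period %.2f h, %s PRC; phase day 1 = %.2f h\n",
              x$config$clock$period,
              if (is.null(x$config$clock$prc)) "no" else "active",
              x$phases[1]))
  invisible(x)
}

#' Write a simulation as generic-dialect CSV files
#'
#' Writes `streams.csv` (generic dialect: `timestamp,stream,value` rows for
#' HR, steps and sleep starts/ends) and `ledger.csv` (ground truth).
#'
#' @param sim a `crhr_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_generic_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- sim$records
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")
  streams <- rbind(
    data.frame(timestamp = fmt(rec$hr$time), stream = "hr",
               value = rec$hr$bpm),
    data.frame(timestamp = fmt(rec$steps$time), stream = "steps",
               value = rec$steps$steps),
    data.frame(timestamp = fmt(rec$sleeps$start), stream = "sleep_start",
               value = 0),
    data.frame(timestamp = fmt(rec$sleeps$end), stream = "sleep_end",
               value = 0))
  streams <- streams[order(streams$timestamp), ]
  p1 <- file.path(dir, "streams.csv")
  p2 <- file.path(dir, "ledger.csv")
  write.csv(streams, p1, row.names = FALSE)
  write.csv(sim$ledger, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
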