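# Reading device exports, 5-minute binning, sleep consolidation, wake-day
# segmentation and 2-day fit-window construction.
#
# All timestamps are civil local time, stored as POSIXct with tz = "UTC" as
# a fixed-offset stand-in (no DST arithmetic; transitions pass through
# as-is).

#' Read wearable device exports
#'
#' Parses heart-rate, step and sleep streams from one of three dialects:
#' \describe{
#'   \item{`generic`}{CSV with columns `timestamp` (ISO-8601), `stream`
#'     (one of `hr`, `steps`, `sleep_start`, `sleep_end`) and `value`.}
#'   \item{`fitbit_split`}{three CSVs per subject: an HR file
#'     (`timestamp,bpm`), a Step file (`timestamp,steps`) and a Sleep_Stage
#'     file (`start,end,stage`; any non-wake stage counts as sleep).  Files
#'     are recognized by name (`sleep`, `step`, otherwise HR).}
#'   \item{`applewatch`}{single CSV `timestamp,hr,steps`, no sleep column
#'     (overnight charging gaps serve as sleep separators; see
#'     [infer_sleep_from_gaps]).}
#' }
#'
#' Unparseable rows are skipped with a warning giving the count; heart rates
#' outside (20, 250) bpm and negative step counts are dropped the same way.
#'
#' @param paths character vector of file paths.
#' @param dialect one of `"generic"`, `"fitbit_split"`, `"applewatch"`.
#' @return an object of class `"crhr_records"`: list with `hr`
#'   (`data.frame(time, bpm)`), `steps` (`data.frame(time, steps)`) and
#'   `sleeps` (`data.frame(start, end)`), each sorted by time.
#' @export
read_device_export <- function(paths, dialect = c("generic", "fitbit_split",
                                                  "applewatch")) {
  dialect <- match.arg(dialect)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  skipped <- 0L
  hr <- list(); st <- list(); sl <- list()

  note_skip <- function(n) skipped <<- skipped + n

  if (dialect == "generic") {
    for (p in paths) {
      d <- read.csv(p, stringsAsFactors = FALSE)
      need <- c("timestamp", "stream", "value")
      if (!all(need %in% names(d)))
        stop("generic dialect needs columns timestamp, stream, value: ", p)
      tm <- suppressWarnings(parse_time(d$timestamp))
      val <- suppressWarnings(as.numeric(d$value))
      bad <- is.na(tm) | (d$stream %in% c("hr", "steps") & is.na(val)) |
        !d$stream %in% c("hr", "steps", "sleep_start", "sleep_end")
      note_skip(sum(bad))
      d <- d[!bad, , drop = FALSE]; tm <- tm[!bad]; val <- val[!bad]
      hr[[p]] <- data.frame(time = tm[d$stream == "hr"],
                            bpm = val[d$stream == "hr"])
      st[[p]] <- data.frame(time = tm[d$stream == "steps"],
                            steps = val[d$stream == "steps"])
      ss <- tm[d$stream == "sleep_start"]; se <- tm[d$stream == "sleep_end"]
      ss <- sort(ss); se <- sort(se)
      n <- min(length(ss), length(se))
      if (length(ss) != length(se))
        warning("unpaired sleep_start/sleep_end rows; extra ones dropped")
      if (n) sl[[p]] <- data.frame(start = ss[seq_len(n)], end = se[seq_len(n)])
    }
  } else if (dialect == "fitbit_split") {
    for (p in paths) {
      bn <- tolower(basename(p))
      d <- read.csv(p, stringsAsFactors = FALSE)
      if (grepl("sleep", bn)) {
        if (nrow(d) == 0) next
        s <- suppressWarnings(parse_time(d[[1]]))
        e <- suppressWarnings(parse_time(d[[2]]))
        stage <- if (ncol(d) >= 3) tolower(as.character(d[[3]])) else "asleep"
        bad <- is.na(s) | is.na(e) | e <= s
        note_skip(sum(bad))
        keep <- !bad & stage != "wake"
        if (any(keep)) sl[[p]] <- data.frame(start = s[keep], end = e[keep])
      } else if (grepl("step", bn)) {
        tm <- suppressWarnings(parse_time(d[[1]]))
        v <- suppressWarnings(as.numeric(d[[2]]))
        bad <- is.na(tm) | is.na(v) | v < 0
        note_skip(sum(bad))
        st[[p]] <- data.frame(time = tm[!bad], steps = v[!bad])
      } else {
        tm <- suppressWarnings(parse_time(d[[1]]))
        v <- suppressWarnings(as.numeric(d[[2]]))
        bad <- is.na(tm) | is.na(v) | v <= 20 | v >= 250
        note_skip(sum(bad))
        hr[[p]] <- data.frame(time = tm[!bad], bpm = v[!bad])
      }
    }
  } else { # applewatch
    for (p in paths) {
      d <- read.csv(p, stringsAsFactors = FALSE)
      need <- c("timestamp", "hr", "steps")
      if (!all(need %in% names(d)))
        stop("applewatch dialect needs columns timestamp, hr, steps: ", p)
      tm <- suppressWarnings(parse_time(d$timestamp))
      h <- suppressWarnings(as.numeric(d$hr))
      s <- suppressWarnings(as.numeric(d$steps))
      bad_t <- is.na(tm)
      note_skip(sum(bad_t))
      keep_h <- !bad_t & !is.na(h) & h > 20 & h < 250
      keep_s <- !bad_t & !is.na(s) & s >= 0
      hr[[p]] <- data.frame(time = tm[keep_h], bpm = h[keep_h])
      st[[p]] <- data.frame(time = tm[keep_s], steps = s[keep_s])
    }
  }

  bind_sorted <- function(lst, tcol) {
    if (!length(lst)) return(NULL)
    d <- do.call(rbind, unname(lst))
    d[order(d[[tcol]]), , drop = FALSE]
  }
  hr_df <- bind_sorted(hr, "time") %||%
    data.frame(time = parse_time(character(0)), bpm = numeric(0))
  st_df <- bind_sorted(st, "time") %||%
    data.frame(time = parse_time(character(0)), steps = numeric(0))
  sl_df <- bind_sorted(sl, "start") %||%
    data.frame(start = parse_time(character(0)), end = parse_time(character(0)))
  rownames(hr_df) <- rownames(st_df) <- rownames(sl_df) <- NULL
  if (skipped > 0)
    warning(sprintf("skipped %d unparseable or out-of-range rows", skipped))
  structure(list(hr = hr_df, steps = st_df, sleeps = sl_df),
            dialect = dialect, n_skipped = skipped, class = "crhr_records")
}

#' @export
print.crhr_records <- function(x, ...) {
  cat(sprintf("Device records (%s): %d HR, %d step, %d sleep intervals\n",
              attr(x, "dialect") %||% "generic",
              nrow(x$hr), nrow(x$steps), nrow(x$sleeps)))
  invisible(x)
}

#' Consolidate sleep intervals
#'
#' Sorts and merges device sleep intervals: overlapping intervals are merged
#' (with a warning), and intervals separated by a wake gap strictly shorter
#' than `max_interruption_hours` are merged into one sleep period — short
#' interruptions in the middle of a longer sleep are absorbed, and the data
#' inside them is later excluded from fitting.
#'
#' @param sleeps a `data.frame(start, end)` or a `crhr_records` object.
#' @param max_interruption_hours wake gaps shorter than this merge
#'   (default 2; a gap of exactly 2 h is kept).
#' @return a `data.frame(start, end, midpoint)` of class `"crhr_sleeps"`.
#' @export
consolidate_sleep <- function(sleeps, max_interruption_hours = 2) {
  if (inherits(sleeps, "crhr_records")) sleeps <- sleeps$sleeps
  if (is.null(sleeps) || nrow(sleeps) == 0) {
    out <- data.frame(start = parse_time(character(0)),
                      end = parse_time(character(0)),
                      midpoint = parse_time(character(0)))
    class(out) <- c("crhr_sleeps", "data.frame")
    return(out)
  }
  stopifnot(all(sleeps$end > sleeps$start))
  o <- order(sleeps$start)
  s <- as.numeric(sleeps$start)[o]; e <- as.numeric(sleeps$end)[o]
  if (any(s[-1] < e[-length(e)]))
    warning("overlapping sleep intervals merged")
  gap_sec <- max_interruption_hours * 3600
  ms <- s[1]; me <- e[1]; out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] - me < gap_sec) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  out <- data.frame(
    start = as.POSIXct(out_s, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(out_e, origin = "1970-01-01", tz = "UTC"))
  out$midpoint <- out$start + (out$end - out$start) / 2
  class(out) <- c("crhr_sleeps", "data.frame")
  out
}

#' Infer sleep separators from charging gaps
#'
#' For exports without sleep labels (e.g. Apple Watch worn all day and
#' charged overnight): heart-rate gaps of at least `min_gap_hours` with zero
#' recorded steps inside are treated as sleep separators.
#'
#' @param records a `crhr_records` object.
#' @param min_gap_hours minimum HR gap length (default 4).
#' @return `data.frame(start, end)` of inferred sleep intervals.
#' @export
infer_sleep_from_gaps <- function(records, min_gap_hours = 4) {
  tm <- as.numeric(records$hr$time)
  if (length(tm) < 2)
    return(data.frame(start = parse_time(character(0)),
                      end = parse_time(character(0))))
  gaps <- which(diff(tm) >= min_gap_hours * 3600)
  st_t <- as.numeric(records$steps$time)
  keep <- vapply(gaps, function(i) {
    inside <- st_t > tm[i] & st_t < tm[i + 1]
    !any(inside) || sum(records$steps$steps[inside]) == 0
  }, logical(1))
  gaps <- gaps[keep]
  data.frame(start = as.POSIXct(tm[gaps], origin = "1970-01-01", tz = "UTC"),
             end = as.POSIXct(tm[gaps + 1], origin = "1970-01-01", tz = "UTC"))
}

#' Bin records to a fixed 5-minute grid
#'
#' Averages heart rate and totals steps into fixed bins, so that periods of
#' more frequent measurement do not disproportionately affect results.  HR
#' per bin is the arithmetic mean of the records falling in it; bins with no
#' HR record are explicitly missing (`NA`), never zero-filled.  Step counts
#' are attributed to bins pro-rata by overlap of each record's native
#' interval (inferred from record spacing), which conserves totals, and
#' reported as a rate in steps per minute.
#'
#' @param records a `crhr_records` object.
#' @param bin_minutes bin length in minutes; must divide 60 (default 5).
#' @param sleeps consolidated sleep periods used to mark bins asleep;
#'   default `consolidate_sleep(records)`.
#' @return a `data.frame(bin_start, hr, steps_per_min, awake)` of class
#'   `"crhr_binned"` with attribute `bin_minutes`.
#' @export
bin_records <- function(records, bin_minutes = 5,
                        sleeps = consolidate_sleep(records)) {
  if (60 %% bin_minutes != 0) stop("bin_minutes must divide 60")
  bin_sec <- bin_minutes * 60
  times <- c(as.numeric(records$hr$time), as.numeric(records$steps$time))
  empty <- data.frame(bin_start = parse_time(character(0)), hr = numeric(0),
                      steps_per_min = numeric(0), awake = logical(0))
  if (!length(times)) {
    attr(empty, "bin_minutes") <- bin_minutes
    class(empty) <- c("crhr_binned", "data.frame")
    return(empty)
  }
  grid0 <- floor(min(times) / bin_sec) * bin_sec
  n_bins <- as.integer(floor((max(times) - grid0) / bin_sec)) + 1L
  bin_start <- grid0 + (seq_len(n_bins) - 1L) * bin_sec

  hr <- rep(NA_real_, n_bins)
  if (nrow(records$hr)) {
    idx <- as.integer(floor((as.numeric(records$hr$time) - grid0) / bin_sec)) + 1L
    sums <- rowsum(records$hr$bpm, idx)
    cnts <- rowsum(rep(1, length(idx)), idx)
    hr[as.integer(rownames(sums))] <- sums / cnts
  }

  steps <- rep(0, n_bins)
  if (nrow(records$steps)) {
    s0 <- as.numeric(records$steps$time)
    v <- records$steps$steps
    dur <- diff(s0)
    native <- if (length(dur)) {
      md <- median(dur[dur > 0])
      if (!is.finite(md) || md <= 0) bin_sec else min(md, 3600)
    } else bin_sec
    dur <- c(dur, native)
    dur[dur <= 0 | dur > 3600] <- native
    s1 <- s0 + dur
    ib0 <- as.integer(floor((s0 - grid0) / bin_sec)) + 1L
    ib1 <- as.integer(floor((s1 - grid0 - 1e-9) / bin_sec)) + 1L
    ib1 <- pmin(ib1, n_bins)
    same <- ib0 == ib1
    if (any(same)) {
      sm <- rowsum(v[same], ib0[same])
      ii <- as.integer(rownames(sm))
      steps[ii] <- steps[ii] + sm
    }
    for (i in which(!same)) {            # records straddling bin boundaries
      for (b in ib0[i]:ib1[i]) {
        lo <- max(s0[i], grid0 + (b - 1) * bin_sec)
        hi <- min(s1[i], grid0 + b * bin_sec)
        steps[b] <- steps[b] + v[i] * (hi - lo) / dur[i]
      }
    }
  }

  awake <- rep(TRUE, n_bins)
  if (!is.null(sleeps) && nrow(sleeps)) {
    ss <- as.numeric(sleeps$start); se <- as.numeric(sleeps$end)
    for (i in seq_along(ss))
      awake[bin_start < se[i] & bin_start + bin_sec > ss[i]] <- FALSE
  }

  out <- data.frame(
    bin_start = as.POSIXct(bin_start, origin = "1970-01-01", tz = "UTC"),
    hr = hr, steps_per_min = steps / bin_minutes, awake = awake)
  attr(out, "bin_minutes") <- bin_minutes
  class(out) <- c("crhr_binned", "data.frame")
  out
}

#' Segment wakefulness into days
#'
#' A "day" is a period of wakefulness bounded by sleep periods strictly
#' longer than `min_separator_hours` (or by record boundaries, in which case
#' it is flagged unbounded).  Shorter sleeps (naps) do not split a day, but
#' their bins are still excluded from every day.
#'
#' @param binned a `crhr_binned` series.
#' @param sleeps consolidated sleep periods ([consolidate_sleep]).
#' @param min_separator_hours sleeps must exceed this to split days
#'   (default 2; a sleep of exactly 2 h does not split).
#' @return list of class `"crhr_days"`; each element has `start`, `end`
#'   (POSIXct), `bins` (row indices into `binned`) and `bounded` (logical:
#'   flanked by qualifying sleeps on both sides).
#' @export
segment_wake_days <- function(binned, sleeps, min_separator_hours = 2) {
  if (nrow(binned) == 0) return(structure(list(), class = "crhr_days"))
  dur_h <- as.numeric(difftime(sleeps$end, sleeps$start, units = "hours"))
  sep <- sleeps[dur_h > min_separator_hours, , drop = FALSE]
  t0 <- binned$bin_start[1]
  bin_sec <- (attr(binned, "bin_minutes") %||% 5) * 60
  t1 <- binned$bin_start[nrow(binned)] + bin_sec
  edges_start <- c(t0, sep$end)
  edges_end <- c(sep$start, t1)
  bounded_l <- c(FALSE, rep(TRUE, nrow(sep)))
  bounded_r <- c(rep(TRUE, nrow(sep)), FALSE)

  days <- list()
  for (i in seq_along(edges_start)) {
    ds <- edges_start[i]; de <- edges_end[i]
    if (as.numeric(difftime(de, ds, units = "mins")) <= 0) next
    in_span <- binned$bin_start >= ds & binned$bin_start < de
    bins <- which(in_span & binned$awake)
    days[[length(days) + 1]] <- list(
      start = ds, end = de, bins = bins,
      bounded = bounded_l[i] && bounded_r[i])
  }
  if (nrow(sep) == 0 && length(days))
    days[[1]]$bounded <- FALSE
  structure(days, class = "crhr_days")
}

#' @export
print.crhr_days <- function(x, ...) {
  cat(sprintf("%d wake day(s):\n", length(x)))
  for (d in x)
    cat(sprintf("  %s to %s (%d awake bins%s)\n",
                format(d$start), format(d$end), length(d$bins),
                if (d$bounded) "" else ", unbounded"))
  invisible(x)
}

#' Build 2-day fit windows
#'
#' One window per interior sleep period: the flanking wake days are paired
#' and their awake, non-missing-HR bins become the observation series, with
#' time measured in hours since local midnight of the first day.  Windows
#' with fewer observations than `min_obs` are dropped with a message.
#'
#' @param days wake days from [segment_wake_days].
#' @param sleeps consolidated sleep periods.
#' @param binned the binned series the day indices refer to.
#' @param min_separator_hours qualifying-sleep threshold (must match
#'   [segment_wake_days]).
#' @param min_obs minimum observations per window (default 48 bins, about
#'   4 h of data).
#' @return list of class `"crhr_windows"`; each `"crhr_window"` element has
#'   `day_before`, `day_after`, `center_sleep` (with `midpoint`),
#'   `observations` (a [gap_series]) and `window_id`.
#' @export
build_fit_windows <- function(days, sleeps, binned, min_separator_hours = 2,
                              min_obs = 48) {
  dur_h <- as.numeric(difftime(sleeps$end, sleeps$start, units = "hours"))
  sep <- sleeps[dur_h > min_separator_hours, , drop = FALSE]
  bin_minutes <- attr(binned, "bin_minutes") %||% 5
  windows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(sep))) {
    before <- Filter(function(d) d$end == sep$start[i], days)
    after <- Filter(function(d) d$start == sep$end[i], days)
    if (!length(before) || !length(after)) next
    before <- before[[1]]; after <- after[[1]]
    bins <- c(before$bins, after$bins)
    bins <- bins[!is.na(binned$hr[bins])]
    midnight1 <- as.POSIXct(trunc(before$start, units = "days"))
    t <- as.numeric(difftime(binned$bin_start[bins], midnight1,
                             units = "hours"))
    if (length(bins) < min_obs) {
      dropped <- dropped + 1L
      next
    }
    obs <- gap_series(t, binned$hr[bins], binned$steps_per_min[bins],
                      bin_minutes = bin_minutes)
    windows[[length(windows) + 1]] <- structure(list(
      day_before = before, day_after = after,
      center_sleep = list(start = sep$start[i], end = sep$end[i],
                          midpoint = sep$start[i] +
                            (sep$end[i] - sep$start[i]) / 2),
      observations = obs,
      midnight1 = midnight1,
      window_id = length(windows) + 1L
    ), class = "crhr_window")
  }
  if (dropped > 0)
    message(sprintf("dropped %d window(s) below the %d-observation floor",
                    dropped, min_obs))
  structure(windows, class = "crhr_windows")
}

#' @export
print.crhr_windows <- function(x, ...) {
  cat(sprintf("%d fit window(s)\n", length(x)))
  if (length(x)) print(windows_manifest(x))
  invisible(x)
}

#' Fit-window manifest
#'
#' @param windows a `crhr_windows` list.
#' @return `data.frame(window_id, day1_date, sleep_midpoint, n_obs)`.
#' @export
windows_manifest <- function(windows) {
  data.frame(
    window_id = vapply(windows, `[[`, integer(1), "window_id"),
    day1_date = vapply(windows, function(w)
      format(w$midnight1, "%Y-%m-%d"), character(1)),
    sleep_midpoint = vapply(windows, function(w)
      format(w$center_sleep$midpoint), character(1)),
    n_obs = vapply(windows, function(w) nrow(w$observations), integer(1)))
}

#' One-call preprocessing pipeline
#'
#' Records to consolidated sleeps, binned series, wake days and 2-day fit
#' windows.
#'
#' @param records a `crhr_records` object.
#' @param bin_minutes bin length (default 5).
#' @param min_obs window observation floor (default 48).
#' @param infer_sleep_gap_hours when the export carries no sleep labels,
#'   HR gaps of at least this many hours with zero steps are used as sleep
#'   separators (default 4).
#' @return list with `sleeps`, `binned`, `days`, `windows`.
#' @export
crhr_preprocess <- function(records, bin_minutes = 5, min_obs = 48,
                            infer_sleep_gap_hours = 4) {
  raw_sleeps <- records$sleeps
  if (is.null(raw_sleeps) || nrow(raw_sleeps) == 0)
    raw_sleeps <- infer_sleep_from_gaps(records, infer_sleep_gap_hours)
  sleeps <- consolidate_sleep(raw_sleeps)
  binned <- bin_records(records, bin_minutes, sleeps = sleeps)
  days <- segment_wake_days(binned, sleeps)
  windows <- build_fit_windows(days, sleeps, binned, min_obs = min_obs)
  list(sleeps = sleeps, binned = binned, days = days, windows = windows)
}
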