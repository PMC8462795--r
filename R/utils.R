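# Circular-hour helpers shared across the package.  Phases live on a 24-h
# circle; differences are reported in (-12, 12] with advance positive.

#' Wrap hours onto the 24-h circle
#'
#' @param h numeric hours.
#' @return `h` modulo 24, in `[0, 24)`.
#' @export
wrap_hours <- function(h) {
  h %% 24
}

#' Wrapped difference of two clock hours
#'
#' Difference `h1 - h2` mapped to the half-open interval `(-12, 12]`.
#'
#' @param h1,h2 numeric hours.
#' @return wrapped difference in hours.
#' @export
wrap_diff <- function(h1, h2 = 0) {
  d <- (h1 - h2) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Circular mean of clock hours
#'
#' Resultant-vector mean of hours mapped to angles `2*pi*h/24`.
#'
#' @param h numeric hours.
#' @param na.rm drop missing values first.
#' @return mean hour in `[0, 24)`, or `NA` if the resultant vanishes.
#' @export
circular_mean_hours <- function(h, na.rm = FALSE) {
  if (na.rm) h <- h[!is.na(h)]
  ang <- h * pi / 12
  s <- mean(sin(ang)); c <- mean(cos(ang))
  if (s == 0 && c == 0) return(NA_real_)
  wrap_hours(atan2(s, c) * 12 / pi)
}

# Central quantile interval of hours about a circular center: quantiles of
# the wrapped deviations, added back to the center.  Returns hours on [0,24).
circular_quantile_hours <- function(h, center, probs) {
  dev <- wrap_diff(h, center)
  wrap_hours(center + quantile(dev, probs, names = FALSE, type = 7))
}

# Hours since local midnight of the civil day containing `origin`.
hours_since_midnight_of <- function(times, origin) {
  mid <- as.POSIXct(trunc(origin, units = "days"))
  as.numeric(difftime(times, mid, units = "hours"))
}

# Clock hour-of-day of a POSIXct (fractional hours in [0,24)).
clock_hours <- function(times) {
  lt <- as.POSIXlt(times)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# Parse timestamps in the device's local civil time.  All internal POSIXct
# use tz = "UTC" as a fixed stand-in for local civil time, so arithmetic is
# DST-free (documented caveat: DST transitions pass through as-is).
# Unparseable entries become NA (callers skip and count them).
parse_time <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
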