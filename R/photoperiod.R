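#' Astronomical daylength (photoperiod)
#'
#' Sunrise-to-sunset daylength in hours from the standard solar-position
#' algorithm: a Fourier-series solar declination evaluated at local noon, and
#' a sunrise/sunset hour angle at solar zenith 90.833 degrees, which accounts
#' for atmospheric refraction and the apparent solar radius.  Where the hour
#' angle has no solution the day is polar: 24 h (midnight sun) or 0 h (polar
#' night).
#'
#' Day-to-day change in photoperiod (`delta_photoperiod()`) is the diapause
#' clock of the model: its sign separates the shortening-day season (diapause
#' induction possible) from the lengthening-day season (diapause termination
#' possible).
#'
#' @param site A [pcmp_site()] (or a single latitude in decimal degrees).
#' @param day_of_year Integer day(s) of year, 1--366.
#' @param year Calendar year, used only to pick the year length (365 or 366).
#'
#' @return Daylength in hours, vectorised over `day_of_year`.
#' @examples
#' photoperiod(tokyo_site(), 172)  # near the summer solstice, ~14.5 h
#' photoperiod(80, 172)            # polar day, 24 h
#' @export
photoperiod <- function(site, day_of_year, year = 2019) {
  lat <- if (inherits(site, "pcmp_site")) site$latitude else site
  if (!is.numeric(lat) || length(lat) != 1 || is.na(lat) || abs(lat) > 90) {
    abort("latitude must be a single number in [-90, 90].",
          class = "pcmp_invalid_site")
  }
  n_days <- if (is_leap_year(year)) 366 else 365
  if (any(day_of_year < 1 | day_of_year > n_days)) {
    abort(sprintf("`day_of_year` must be in [1, %d].", n_days),
          class = "pcmp_invalid_doy")
  }
  gamma <- 2 * pi / n_days * (day_of_year - 1)
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  lat_r <- lat * pi / 180
  # cos of the sunrise/sunset hour angle at zenith 90.833 deg
  cos_ha <- cos(90.833 * pi / 180) / (cos(lat_r) * cos(decl)) -
    tan(lat_r) * tan(decl)
  cos_ha <- pmin(pmax(cos_ha, -1), 1)   # polar day (-1) / polar night (+1)
  2 * acos(cos_ha) * 180 / pi / 15
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Day-to-day change in photoperiod
#'
#' First difference of a daily daylength series.  The first element copies the
#' second so that the series has the same length as the input and the sign of
#' the change — which gates diapause induction (negative) versus termination
#' (positive) — is never undefined at the series boundary.
#'
#' @param d Numeric vector of daily photoperiods (hours), at least 2 days.
#' @return Numeric vector of the same length: `d[t] - d[t - 1]`, with the
#'   first element equal to the second.
#' @examples
#' delta_photoperiod(photoperiod(tokyo_site(), 1:10))
#' @export
delta_photoperiod <- function(d) {
  if (length(d) < 2) {
    abort("need at least 2 consecutive days to difference a photoperiod series.",
          class = "pcmp_insufficient_series")
  }
  dd <- c(NA_real_, diff(d))
  dd[1] <- dd[2]
  dd
}

#' Trailing 7-day mean
#'
#' Mean of the most recent 7 days (the current day and the 6 before it).  For
#' the first 6 days of a series, where a full week of history does not exist,
#' the mean of all available days is used.
#'
#' @param x Non-empty numeric vector of daily values.
#' @return Numeric vector of the same length.
#' @examples
#' rolling_week_mean(1:7)  # last element is 4
#' @export
rolling_week_mean <- function(x) {
  n <- length(x)
  if (n == 0) {
    abort("cannot take a rolling mean of an empty series.",
          class = "pcmp_insufficient_series")
  }
  s <- cumsum(x)
  out <- numeric(n)
  head_n <- seq_len(min(7, n))
  out[head_n] <- s[head_n] / head_n
  if (n > 7) {
    t <- 8:n
    out[t] <- (s[t] - s[t - 7]) / 7
  }
  out
}
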