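#' Seasonal summary of a simulated trajectory
#'
#' Aggregates a daily trajectory into weekly mean adult abundances per year,
#' averages the weekly series across years, and extracts the seasonal
#' descriptors: peak of the averaged weekly dynamics, peak week (earliest
#' week on ties), and season onset/termination — the first and last weeks at
#' which the averaged adults reach a threshold fraction of the peak.
#'
#' @param trajectory A [simulate_population()] trajectory.
#' @param years Calendar years to include; `NULL` (default) keeps every
#'   complete year.  Incomplete years are excluded with a warning.
#' @param season_threshold Fraction of the peak defining the active season
#'   (default 0.05).
#' @return An object of class `pcmp_summary`: weekly and averaged series
#'   plus `peak`, `peak_week`, `onset_week`, `termination_week`.  Has
#'   [tidy()] and [glance()] methods.
#' @export
summarize_scenario <- function(trajectory, years = NULL, season_threshold = 0.05) {
  yr <- as.integer(format(trajectory$date, "%Y"))
  days_per_year <- table(yr)
  expected <- ifelse(is_leap_year(as.integer(names(days_per_year))), 366, 365)
  complete <- as.integer(names(days_per_year))[days_per_year == expected]
  keep <- if (is.null(years)) complete else intersect(years, complete)
  dropped <- setdiff(if (is.null(years)) unique(yr) else years, keep)
  if (length(dropped) > 0) {
    warn(sprintf("excluding incomplete year(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  if (length(keep) == 0) abort("no complete year to summarize.")

  sub <- trajectory[yr %in% keep, , drop = FALSE]
  weekly <- sub |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  week = week_of_year(.data$date)) |>
    dplyr::group_by(.data$year, .data$week) |>
    dplyr::summarise(mean_adults = mean(.data$A), .groups = "drop")
  averaged <- weekly |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(mean_adults = mean(.data$mean_adults), .groups = "drop") |>
    dplyr::arrange(.data$week)

  peak <- max(averaged$mean_adults)
  peak_week <- averaged$week[which.max(averaged$mean_adults)]  # earliest on ties
  active <- averaged$week[averaged$mean_adults >= season_threshold * peak]
  structure(
    list(weekly = weekly, averaged = averaged, peak = peak,
         peak_week = as.integer(peak_week),
         onset_week = as.integer(min(active)),
         termination_week = as.integer(max(active)),
         season_threshold = season_threshold, years = keep),
    class = "pcmp_summary"
  )
}

#' @export
print.pcmp_summary <- function(x, ...) {
  cat("<pcmp_summary>\n")
  cat(sprintf("  years: %s\n", paste(range(x$years), collapse = "-")))
  cat(sprintf("  peak averaged adults: %.2f at week %d\n", x$peak, x$peak_week))
  cat(sprintf("  active season: weeks %d-%d (threshold %.0f%% of peak)\n",
              x$onset_week, x$termination_week, 100 * x$season_threshold))
  invisible(x)
}

peak_of <- function(x) {
  if (inherits(x, "pcmp_summary")) x$peak
  else if (is.numeric(x) && length(x) == 1) x
  else abort("expected a pcmp_summary or a single peak value.")
}

#' Peak-abundance ratio between two model variants
#'
#' Ratio of the peaks of two averaged weekly dynamics (`a / b`), reported to
#' two decimals — the convention used to compare the rainfall-responsive
#' (`nu = 1`) and fixed-capacity (`nu = 0`) model variants under a common
#' climate scenario.
#'
#' @param summary_a,summary_b [summarize_scenario()] results (or bare peak
#'   values).
#' @return The peak ratio, rounded to 2 decimals.
#' @examples
#' compare_models(77.6, 57.4)  # 1.35
#' @export
compare_models <- function(summary_a, summary_b) {
  pb <- peak_of(summary_b)
  if (pb == 0) abort("denominator peak is zero.")
  round(peak_of(summary_a) / pb, 2)
}

#' Climate-input bias ratio
#'
#' Ratio of peak averaged abundance obtained with one climate input (e.g. a
#' climate-model series) to that obtained with another (e.g. observations),
#' holding the population model fixed.  Scenario ratios can be bias-corrected
#' by dividing a raw ratio by this bias.
#'
#' @param summary_model_climate Summary driven by the scenario/model climate.
#' @param summary_obs_climate Summary driven by the reference climate.
#' @return The (unrounded) bias ratio.
#' @export
compute_bias <- function(summary_model_climate, summary_obs_climate) {
  peak_of(summary_model_climate) / peak_of(summary_obs_climate)
}

#' Frequency histogram of a habitat driver
#'
#' Bins a daily driver series the way the model's climate-input diagnostics
#' are drawn: precipitation gets a dedicated zero bin (dry days) followed by
#' uniform-width bins; the soil moisture ratio is binned on 0--100 %.
#'
#' @param x Numeric series: daily precipitation (mm) or soil moisture ratio.
#'   For `"soil_moisture_ratio"`, values may be given as a 0--1 fraction or
#'   0--100 %.
#' @param variable `"precipitation"` or `"soil_moisture_ratio"`.
#' @param bin_width Bin width (mm, or percentage points); default 5.
#' @return A tibble with `bin`, `lower`, `upper`, `count`, `frequency`;
#'   counts sum to `length(x)`.
#' @export
driver_histogram <- function(x, variable = c("precipitation", "soil_moisture_ratio"),
                             bin_width = 5) {
  variable <- match.arg(variable)
  if (length(x) == 0) abort("empty series.")
  if (variable == "precipitation") {
    zero <- sum(x == 0)
    pos <- x[x > 0]
    top <- if (length(pos) > 0) ceiling(max(pos) / bin_width) * bin_width else bin_width
    breaks <- seq(0, top, by = bin_width)
    counts <- if (length(pos) > 0) {
      as.integer(table(cut(pos, breaks = breaks, include.lowest = FALSE)))
    } else {
      integer(length(breaks) - 1)
    }
    out <- tibble::tibble(
      bin = c("0", sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1])),
      lower = c(0, breaks[-length(breaks)]),
      upper = c(0, breaks[-1]),
      count = c(zero, counts)
    )
  } else {
    if (max(x) <= 1) x <- 100 * x
    if (any(x < 0 | x > 100)) abort("soil moisture ratio must lie in [0, 100] %.")
    breaks <- seq(0, 100, by = bin_width)
    counts <- as.integer(table(cut(x, breaks = breaks, include.lowest = TRUE)))
    out <- tibble::tibble(
      bin = sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1]),
      lower = breaks[-length(breaks)],
      upper = breaks[-1],
      count = counts
    )
  }
  out$frequency <- out$count / length(x)
  out
}

#' Apply a uniform climate shift to a weather series
#'
#' Emulates warming/precipitation-change scenarios without climate-model
#' output: air temperature is shifted uniformly and wet-day precipitation
#' amounts are scaled; all other variables are unchanged.
#'
#' @param weather Daily weather tibble.
#' @param delta_t Additive temperature shift (degrees C).
#' @param precip_scale Multiplicative factor on precipitation amounts, >= 0.
#' @return The shifted weather tibble.
#' @export
scenario_shift <- function(weather, delta_t = 0, precip_scale = 1) {
  stopifnot(is.finite(delta_t), precip_scale >= 0)
  weather$t_air <- weather$t_air + delta_t
  weather$precip <- weather$precip * precip_scale
  weather
}
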