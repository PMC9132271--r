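#' Read a daily weather series
#'
#' Reads the comma-separated daily weather dialect used throughout the
#' package: one header row, ISO-8601 dates, columns
#' `date,t_air,precip,rel_humidity,solar_rad,wind,cloud`.  Every physical
#' invariant is checked and violations are reported with their row numbers;
#' the date column must be strictly increasing with no gaps.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one validated row per day.
#' @seealso [read_traps()], [generate_weather()]
#' @export
read_weather <- function(path) {
  wx <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("date", "t_air", "precip", "rel_humidity", "solar_rad", "wind", "cloud")
  missing_cols <- setdiff(needed, names(wx))
  if (length(missing_cols) > 0) {
    abort(sprintf("weather file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pcmp_format_error")
  }
  wx <- dplyr::select(wx, dplyr::all_of(needed))
  if (!inherits(wx$date, "Date")) {
    parsed <- as.Date(as.character(wx$date), format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      abort(sprintf("unparsable date(s) at row(s): %s",
                    paste(utils::head(which(is.na(parsed)), 5), collapse = ", ")),
            class = "pcmp_format_error")
    }
    wx$date <- parsed
  }
  validate_weather(wx)
  wx
}

validate_weather <- function(wx) {
  bad_row <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort(sprintf("%s at row(s): %s", what,
                    paste(utils::head(rows, 5), collapse = ", ")),
            class = "pcmp_format_error")
    }
  }
  bad_row(is.na(wx$t_air), "missing air temperature")
  bad_row(!is.na(wx$precip) & wx$precip < 0, "negative precipitation")
  bad_row(is.na(wx$precip), "missing precipitation")
  bad_row(wx$rel_humidity < 0 | wx$rel_humidity > 100, "relative humidity outside [0, 100]")
  bad_row(wx$cloud < 0 | wx$cloud > 1, "cloud amount outside [0, 1]")
  bad_row(wx$wind < 0, "negative wind speed")
  dups <- duplicated(wx$date)
  if (any(dups)) {
    abort(sprintf("duplicate date(s): %s",
                  paste(utils::head(format(wx$date[dups]), 5), collapse = ", ")),
          class = "pcmp_format_error")
  }
  if (is.unsorted(wx$date, strictly = TRUE)) {
    abort("dates are not strictly increasing.", class = "pcmp_format_error")
  }
  step <- diff(as.integer(wx$date))
  if (any(step != 1)) {
    gap_at <- which(step != 1)[1]
    missing_dates <- seq(wx$date[gap_at] + 1, wx$date[gap_at + 1] - 1, by = "day")
    abort(sprintf("gap in daily dates; missing: %s",
                  paste(utils::head(format(missing_dates), 10), collapse = ", ")),
          class = "pcmp_format_error")
  }
  invisible(wx)
}

#' Read weekly trap observations
#'
#' Reads a weekly adult-female trap-count series: CSV with columns
#' `date` (collection date, ISO-8601) and `count` (nonnegative integer).
#' Each observation is assigned to the 7-day week-of-year block containing
#' its collection date (week w covers days `7(w-1)+1 ... 7w` from Jan 1).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `date`, `year`, `week_index`, `count`.
#' @export
read_traps <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("date", "count")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols) > 0) {
    abort(sprintf("trap file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pcmp_format_error")
  }
  if (!inherits(tr$date, "Date")) {
    parsed <- as.Date(as.character(tr$date), format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      abort(sprintf("unparsable date(s) at row(s): %s",
                    paste(utils::head(which(is.na(parsed)), 5), collapse = ", ")),
            class = "pcmp_format_error")
    }
    tr$date <- parsed
  }
  bad <- which(is.na(tr$count) | tr$count < 0 | tr$count != floor(tr$count))
  if (length(bad) > 0) {
    abort(sprintf("counts must be nonnegative integers; bad row(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")),
          class = "pcmp_format_error")
  }
  out <- tibble::tibble(
    date = tr$date,
    year = as.integer(format(tr$date, "%Y")),
    week_index = week_of_year(tr$date),
    count = as.integer(tr$count)
  )
  if (anyDuplicated(out[c("year", "week_index")]) > 0) {
    abort("more than one observation in the same (year, week) block.",
          class = "pcmp_format_error")
  }
  out
}

#' Week-of-year block of a date
#'
#' Week `w` covers days `7(w-1)+1 ... 7w` counted from January 1, so weeks
#' 1--52 are full 7-day blocks and week 53 holds the final 1--2 days.
#'
#' @param date A `Date` vector.
#' @return Integer week indices (1--53).
#' @export
week_of_year <- function(date) {
  doy <- as.integer(format(date, "%j"))
  as.integer((doy - 1) %/% 7L + 1L)
}
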