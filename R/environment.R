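#' Derive the daily environmental drivers from weather
#'
#' Turns a validated daily weather series into the drivers the population
#' model consumes: astronomical photoperiod and its day-to-day change,
#' container water temperature, soil water content, and the trailing 7-day
#' means of photoperiod, air temperature, and water temperature that cue
#' diapause.
#'
#' @param weather Daily weather tibble (see [read_weather()] or
#'   [generate_weather()]); must be gap-free and valid.
#' @param site A [pcmp_site()].
#' @param config A [habitat_config()].
#'
#' @return A tibble with one row per day and columns `date`, `doy`,
#'   `photoperiod`, `delta_d`, `t_air`, `t_water`, `soil_water`, `w_star`,
#'   `d_week`, `ta_week`, `tw_week`.
#' @examples
#' wx <- generate_weather(weather_gen_config(seed = 1), n_years = 1)
#' env <- build_environment(wx, tokyo_site())
#' @export
build_environment <- function(weather, site, config = habitat_config()) {
  validate_weather(weather)
  if (!inherits(site, "pcmp_site")) {
    abort("`site` must be a pcmp_site object.", class = "pcmp_invalid_site")
  }
  yr <- as.integer(format(weather$date, "%Y"))
  doy <- as.integer(format(weather$date, "%j"))
  d <- unlist(lapply(unique(yr), function(y) {
    photoperiod(site, doy[yr == y], y)
  }), use.names = FALSE)
  tw <- water_temperature(weather, config)
  swb <- soil_water_balance(weather, site, config)
  tibble::tibble(
    date = weather$date,
    doy = doy,
    photoperiod = d,
    delta_d = delta_photoperiod(d),
    t_air = weather$t_air,
    t_water = tw,
    soil_water = swb$soil_water,
    w_star = site$w_star,
    d_week = rolling_week_mean(d),
    ta_week = rolling_week_mean(weather$t_air),
    tw_week = rolling_week_mean(tw)
  )
}
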