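#' Habitat sub-model configuration
#'
#' Parameters of the two habitat drivers derived from daily weather: the
#' container water temperature and the soil water bucket.
#'
#' Water temperature relaxes each day toward an equilibrium temperature
#' computed from an energy balance of a small open container:
#' air temperature, plus absorbed shortwave radiation, minus a cloud-adjusted
#' net longwave loss, minus a latent (evaporative) loss that grows with the
#' saturation deficit and with wind.  The soil bucket gains rain and degree-day
#' snowmelt and loses actual evapotranspiration (potential evapotranspiration
#' scaled by the soil moisture ratio), capped at the site's water-holding
#' capacity `w_star`.
#'
#' @param tw_rate Daily fraction of the gap to equilibrium closed per day,
#'   in (0, 1].  Small containers equilibrate fast; default 0.5/day.
#' @param albedo Water surface shortwave albedo (default 0.08).
#' @param sw_coef Warming per unit absorbed shortwave radiation
#'   (degrees C per MJ m-2 day-1; default 0.15).
#' @param lw_coef Clear-sky net longwave cooling (degrees C; default 0.5),
#'   reduced by cloud cover as `(1 - 0.8 * cloud)`.
#' @param evap_coef Evaporative cooling at zero relative humidity, no wind
#'   (degrees C; default 2).
#' @param wind_coef Relative increase of evaporative cooling per m/s of wind
#'   (default 0.2).
#' @param melt_coef Degree-day snowmelt coefficient (mm per degree C per day;
#'   default 3).
#' @param snow_temp Air temperature below which precipitation falls as snow
#'   (degrees C; default 0).
#' @param initial_soil_water Soil water on the first day; `NULL` (default)
#'   starts the bucket full (`w_star`), a winter wet-soil start.
#' @param initial_snowpack Snowpack water equivalent on the first day (mm).
#'
#' @return A list of class `pcmp_habitat_config`.
#' @export
habitat_config <- function(tw_rate = 0.5, albedo = 0.08, sw_coef = 0.15,
                           lw_coef = 0.5, evap_coef = 2, wind_coef = 0.2,
                           melt_coef = 3, snow_temp = 0,
                           initial_soil_water = NULL, initial_snowpack = 0) {
  stopifnot(tw_rate > 0, tw_rate <= 1, albedo >= 0, albedo < 1,
            sw_coef >= 0, lw_coef >= 0, evap_coef >= 0, wind_coef >= 0,
            melt_coef >= 0, initial_snowpack >= 0)
  structure(
    list(tw_rate = tw_rate, albedo = albedo, sw_coef = sw_coef,
         lw_coef = lw_coef, evap_coef = evap_coef, wind_coef = wind_coef,
         melt_coef = melt_coef, snow_temp = snow_temp,
         initial_soil_water = initial_soil_water,
         initial_snowpack = initial_snowpack),
    class = "pcmp_habitat_config"
  )
}

#' Equilibrium water temperature of the energy balance
#'
#' The fixed point toward which [water_temperature()] relaxes on each day:
#' `Ta + sw_coef * (1 - albedo) * solar - lw_coef * (1 - 0.8 * cloud)
#'  - evap_coef * (1 - RH/100) * (1 + wind_coef * wind)`.
#'
#' @param weather Daily weather tibble (see [read_weather()]).
#' @param config A [habitat_config()].
#' @return Numeric vector of equilibrium temperatures (degrees C).
#' @export
water_equilibrium_temperature <- function(weather, config = habitat_config()) {
  weather$t_air +
    config$sw_coef * (1 - config$albedo) * weather$solar_rad -
    config$lw_coef * (1 - 0.8 * weather$cloud) -
    config$evap_coef * (1 - weather$rel_humidity / 100) *
      (1 + config$wind_coef * weather$wind)
}

#' Daily container water temperature
#'
#' First-order relaxation toward the day's energy-balance equilibrium:
#' `Tw(t) = Tw(t-1) + tw_rate * (Teq(t) - Tw(t-1))`, floored at 0 (ice).
#' With `tw_rate` in (0, 1] the response to a step change in forcing is
#' monotone with no overshoot.
#'
#' @inheritParams water_equilibrium_temperature
#' @return Numeric vector of daily mean water temperatures (degrees C).
#' @export
water_temperature <- function(weather, config = habitat_config()) {
  teq <- water_equilibrium_temperature(weather, config)
  n <- length(teq)
  tw <- numeric(n)
  prev <- max(teq[1], 0)
  tw[1] <- prev
  r <- config$tw_rate
  for (t in seq_len(n)[-1]) {
    prev <- max(prev + r * (teq[t] - prev), 0)
    tw[t] <- prev
  }
  tw
}

#' Potential evapotranspiration (Thornthwaite)
#'
#' Monthly Thornthwaite potential evapotranspiration distributed to days.
#' For each calendar year, monthly mean air temperatures give the annual heat
#' index `I = sum((Tm/5)^1.514)` over months with `Tm > 0` and the exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`; the standard-month
#' value `16 (10 Tm / I)^a` mm is then spread over the month's days in
#' proportion to daylength (the usual daylength/month-length correction,
#' applied at daily resolution).  Days with mean air temperature at or below
#' 0 degrees C get zero.
#'
#' @param weather Daily weather tibble with `date` and `t_air`.
#' @param site A [pcmp_site()] (latitude sets daylength).
#' @return Numeric vector of daily potential evapotranspiration (mm/day).
#' @export
potential_evapotranspiration <- function(weather, site) {
  date <- weather$date
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  doy <- as.integer(format(date, "%j"))
  dl <- unlist(lapply(unique(yr), function(y) {
    idx <- yr == y
    photoperiod(site, doy[idx], y)
  }), use.names = FALSE)

  pet <- numeric(length(date))
  for (y in unique(yr)) {
    iy <- which(yr == y)
    tm <- tapply(weather$t_air[iy], mo[iy], mean)
    tm_pos <- pmax(tm, 0)
    heat_i <- sum((tm_pos[tm_pos > 0] / 5)^1.514)
    if (heat_i <= 0) next
    a <- 6.75e-7 * heat_i^3 - 7.71e-5 * heat_i^2 + 1.792e-2 * heat_i + 0.49239
    pet_month <- ifelse(tm_pos > 0, 16 * (10 * tm_pos / heat_i)^a, 0)
    for (m in names(tm)) {
      im <- iy[mo[iy] == as.integer(m)]
      # spread the standard-month total over days, weighted by daylength
      pet[im] <- pet_month[[m]] * (dl[im] / 12) / 30
    }
  }
  pet[weather$t_air <= 0] <- 0
  pet
}

#' Soil water bucket balance
#'
#' Daily soil water from a single-bucket balance: input is rain plus
#' degree-day snowmelt (precipitation falls as snow below `snow_temp`),
#' output is actual evapotranspiration — potential evapotranspiration scaled
#' by the soil moisture ratio `W / w_star` — and overflow beyond the holding
#' capacity.  Water content is confined to `[0, w_star]`; the returned
#' components close the mass balance exactly:
#' `sum(precip + nothing) - sum(aet) - sum(overflow) = dW + d(snowpack)`.
#'
#' @param weather Daily weather tibble.
#' @param site A [pcmp_site()]; `site$w_star` is the bucket size (mm).
#' @param config A [habitat_config()].
#' @param pet Optional precomputed daily potential evapotranspiration;
#'   computed with [potential_evapotranspiration()] when `NULL`.
#' @return A tibble with columns `date`, `rain`, `snowfall`, `melt`, `pet`,
#'   `aet`, `overflow`, `snowpack`, `soil_water`.
#' @export
soil_water_balance <- function(weather, site, config = habitat_config(),
                               pet = NULL) {
  if (is.null(pet)) pet <- potential_evapotranspiration(weather, site)
  n <- nrow(weather)
  w_star <- site$w_star
  snow_day <- weather$t_air < config$snow_temp
  rain <- ifelse(snow_day, 0, weather$precip)
  snowfall <- ifelse(snow_day, weather$precip, 0)

  w <- if (is.null(config$initial_soil_water)) w_star else config$initial_soil_water
  stopifnot(w >= 0, w <= w_star)
  snow <- config$initial_snowpack

  melt <- aet <- overflow <- snowpack <- soil_water <- numeric(n)
  for (t in seq_len(n)) {
    m <- min(snow + snowfall[t], config$melt_coef * max(weather$t_air[t], 0))
    snow <- snow + snowfall[t] - m
    supply <- w + rain[t] + m
    e <- min(pet[t] * w / w_star, supply)
    w_new <- supply - e
    ov <- max(w_new - w_star, 0)
    w <- w_new - ov
    melt[t] <- m; aet[t] <- e; overflow[t] <- ov
    snowpack[t] <- snow; soil_water[t] <- w
  }
  tibble::tibble(date = weather$date, rain = rain, snowfall = snowfall,
                 melt = melt, pet = pet, aet = aet, overflow = overflow,
                 snowpack = snowpack, soil_water = soil_water)
}
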