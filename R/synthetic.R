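#' Synthetic weather generator configuration
#'
#' A seeded stochastic weather generator with Tokyo-like structure: a
#' seasonal sinusoid plus AR(1) noise for air temperature; a two-state
#' Markov chain for precipitation occurrence with gamma-distributed wet-day
#' amounts (giving the zero-inflated, right-skewed daily rainfall
#' distribution the habitat sub-model responds to); and clipped seasonal
#' sinusoids plus Gaussian noise for humidity, radiation, wind, and cloud.
#'
#' Defaults approximate Tokyo: annual mean 16 degrees C, seasonal amplitude
#' 10 degrees C peaking near day 220, ~36 % wet days averaging ~11.5 mm
#' (~1500 mm/yr).
#'
#' @param mean_temp Annual mean air temperature (degrees C).
#' @param amplitude Seasonal half-range of air temperature (degrees C).
#' @param peak_doy Day of year of the temperature maximum.
#' @param ar_coef,ar_sd AR(1) temperature noise: lag-1 coefficient and
#'   innovation standard deviation (degrees C).
#' @param p_wet_after_dry,p_wet_after_wet Markov precipitation-occurrence
#'   probabilities.
#' @param gamma_shape,gamma_scale Wet-day amount distribution (mm).
#' @param rh_base,rh_amplitude,rh_sd Relative humidity (%): annual mean,
#'   seasonal amplitude (peaking with temperature), noise sd.
#' @param solar_base,solar_amplitude,solar_peak_doy,solar_sd Daily shortwave
#'   radiation (MJ m-2 day-1) seasonal cycle and noise.
#' @param wind_mean,wind_sd Daily mean wind speed (m/s).
#' @param cloud_base,cloud_sd Cloud amount (fraction 0--1).
#' @param seed RNG seed.
#' @return A list of class `pcmp_weather_gen_config`.
#' @export
weather_gen_config <- function(mean_temp = 16, amplitude = 10, peak_doy = 220,
                               ar_coef = 0.7, ar_sd = 1.5,
                               p_wet_after_dry = 0.25, p_wet_after_wet = 0.55,
                               gamma_shape = 0.8, gamma_scale = 14.4,
                               rh_base = 70, rh_amplitude = 8, rh_sd = 5,
                               solar_base = 14, solar_amplitude = 6,
                               solar_peak_doy = 160, solar_sd = 2,
                               wind_mean = 3, wind_sd = 0.8,
                               cloud_base = 0.55, cloud_sd = 0.15,
                               seed = 1) {
  stopifnot(p_wet_after_dry >= 0, p_wet_after_dry <= 1,
            p_wet_after_wet >= 0, p_wet_after_wet <= 1,
            ar_sd >= 0, rh_sd >= 0, solar_sd >= 0, wind_sd >= 0, cloud_sd >= 0,
            gamma_shape > 0, gamma_scale > 0)
  structure(as.list(environment()), class = "pcmp_weather_gen_config")
}

#' Generate a synthetic daily weather series
#'
#' Draws a gap-free, calendar-dated daily weather series from a
#' [weather_gen_config()].  Reproducible given the config's seed; the output
#' passes the same validation as [read_weather()].
#'
#' @param config A [weather_gen_config()].
#' @param n_years Number of calendar years to generate (>= 1).
#' @param start_year First calendar year (default 2001).
#' @return A daily weather tibble.
#' @examples
#' wx <- generate_weather(weather_gen_config(seed = 42), n_years = 2)
#' @export
generate_weather <- function(config, n_years, start_year = 2001) {
  if (!inherits(config, "pcmp_weather_gen_config")) {
    abort("`config` must be a weather_gen_config.", class = "pcmp_invalid_config")
  }
  if (n_years < 1) abort("`n_years` must be >= 1.", class = "pcmp_invalid_config")
  set.seed(config$seed)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  season <- cos(2 * pi * (doy - config$peak_doy) / 365)

  ar <- numeric(n)
  innov <- rnorm(n, 0, config$ar_sd)
  ar[1] <- innov[1]
  for (t in 2:n) ar[t] <- config$ar_coef * ar[t - 1] + innov[t]
  t_air <- config$mean_temp + config$amplitude * season + ar

  wet <- logical(n)
  u <- runif(n)
  wet[1] <- u[1] < config$p_wet_after_dry
  for (t in 2:n) {
    p <- if (wet[t - 1]) config$p_wet_after_wet else config$p_wet_after_dry
    wet[t] <- u[t] < p
  }
  precip <- numeric(n)
  precip[wet] <- rgamma(sum(wet), shape = config$gamma_shape,
                        scale = config$gamma_scale)

  rh <- pmin(pmax(config$rh_base + config$rh_amplitude * season +
                    rnorm(n, 0, config$rh_sd), 5), 100)
  solar_season <- cos(2 * pi * (doy - config$solar_peak_doy) / 365)
  solar <- pmax(config$solar_base + config$solar_amplitude * solar_season +
                  rnorm(n, 0, config$solar_sd), 0.5)
  wind <- pmax(rnorm(n, config$wind_mean, config$wind_sd), 0)
  cloud <- pmin(pmax(config$cloud_base + rnorm(n, 0, config$cloud_sd), 0), 1)

  tibble::tibble(date = dates, t_air = t_air, precip = precip,
                 rel_humidity = rh, solar_rad = solar, wind = wind,
                 cloud = cloud)
}

#' Trap-count generator configuration
#'
#' @param params True [model_params()] used for the forward run.
#' @param site A [pcmp_site()].
#' @param obs_weeks Observation weeks within each year (default 1--52).
#' @param burn_in_years Leading years excluded from observation (default 1).
#' @param seed RNG seed for the Poisson draws.
#' @return A list of class `pcmp_trap_gen_config`.
#' @export
trap_gen_config <- function(params = model_params(), site = tokyo_site(),
                            obs_weeks = 1:52, burn_in_years = 1, seed = 1) {
  stopifnot(inherits(params, "pcmp_model_params"), inherits(site, "pcmp_site"),
            all(obs_weeks >= 1), all(obs_weeks <= 53), burn_in_years >= 0)
  structure(list(params = params, site = site, obs_weeks = obs_weeks,
                 burn_in_years = burn_in_years, seed = seed),
            class = "pcmp_trap_gen_config")
}

#' Generate synthetic weekly trap counts from a known-parameter run
#'
#' Runs the full forward model on a weather series with known ("true")
#' parameters, converts the adult trajectory to expected weekly captures,
#' and draws observed counts from the Poisson observation model.  The truth
#' record (parameters, expectations, trajectory) is returned alongside so
#' parameter-recovery experiments can compare estimates against it.
#'
#' @param weather Daily weather tibble covering the burn-in and observation
#'   years.
#' @param config A [trap_gen_config()].
#' @return A list with `observations` (tibble: `date`, `year`, `week_index`,
#'   `count`) and `truth` (list: `params`, `lambda`, `trajectory`, `env`).
#' @export
generate_trap_counts <- function(weather, config = trap_gen_config()) {
  env <- build_environment(weather, config$site)
  traj <- simulate_population(env, config$params)
  yrs <- unique(as.integer(format(weather$date, "%Y")))
  obs_years <- yrs[-seq_len(config$burn_in_years)]
  if (length(obs_years) == 0) {
    abort("weather does not extend past the burn-in.", class = "pcmp_coverage_error")
  }
  grid <- tidyr::expand_grid(year = obs_years, week_index = as.integer(config$obs_weeks))
  grid <- expected_weekly_capture(traj, grid, config$params$capture_rate)
  set.seed(config$seed)
  grid$count <- rpois(nrow(grid), grid$lambda)
  obs <- tibble::tibble(
    date = as.Date(sprintf("%d-01-01", grid$year)) + 7L * (grid$week_index - 1L),
    year = grid$year,
    week_index = grid$week_index,
    count = as.integer(grid$count)
  )
  list(observations = obs,
       truth = list(params = config$params, lambda = grid, trajectory = traj,
                    env = env))
}

#' Write a small canonical fixture bundle
#'
#' Writes the synthetic fixture used by the test-suite and documentation:
#' a 3-year synthetic weather CSV, a trap-count CSV with 2 observed years
#' after a 1-year burn-in, and the truth record, all derived from one seed.
#'
#' @param seed Seed shared by the weather and count generators.
#' @param dir Output directory (created if needed).
#' @param n_years Weather years (default 3; 1 burn-in + 2 observed).
#' @param params True model parameters for the forward run.
#' @param site The site.
#' @return Invisibly, a list with `weather_path`, `traps_path`, and `truth`.
#' @export
make_fixture_bundle <- function(seed, dir = tempfile("pcmp-fixture-"),
                                n_years = 3, params = model_params(),
                                site = tokyo_site()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wx <- generate_weather(weather_gen_config(seed = seed), n_years = n_years)
  gen <- generate_trap_counts(wx, trap_gen_config(params = params, site = site,
                                                  seed = seed))
  weather_path <- file.path(dir, "weather.csv")
  traps_path <- file.path(dir, "traps.csv")
  readr::write_csv(wx, weather_path)
  readr::write_csv(gen$observations[c("date", "count")], traps_path)
  invisible(list(weather_path = weather_path, traps_path = traps_path,
                 truth = gen$truth))
}
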