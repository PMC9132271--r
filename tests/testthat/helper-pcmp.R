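# Shared fixtures, built in code.

# A constant-weather series of n days starting 2001-01-01.
const_weather <- function(n, t_air = 20, precip = 0, rel_humidity = 70,
                          solar_rad = 12, wind = 2, cloud = 0.5) {
  tibble::tibble(
    date = seq(as.Date("2001-01-01"), by = "day", length.out = n),
    t_air = t_air, precip = precip, rel_humidity = rel_humidity,
    solar_rad = solar_rad, wind = wind, cloud = cloud
  )
}

# Deterministic (noise-free, rain-free) seasonal weather: a pure sinusoid
# temperature cycle, constant humidity/radiation/wind/cloud.
sinusoid_weather <- function(n_years, start_year = 2001) {
  generate_weather(
    weather_gen_config(ar_sd = 0, p_wet_after_dry = 0, p_wet_after_wet = 0,
                       rh_sd = 0, solar_sd = 0, wind_sd = 0, cloud_sd = 0,
                       seed = 1),
    n_years = n_years, start_year = start_year
  )
}

# Default small synthetic world shared by several tests.
test_world <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      wx <- generate_weather(weather_gen_config(seed = 42), n_years = 3)
      env <- build_environment(wx, tokyo_site())
      memo <<- list(weather = wx, env = env)
    }
    memo
  }
})
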