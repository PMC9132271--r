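make_traj <- function(adults_by_doy, years = 2003) {
  purrr::map_dfr(years, function(y) {
    dates <- seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
                 by = "day")
    tibble::tibble(date = dates, A = adults_by_doy(as.integer(format(dates, "%j"))))
  })
}

test_that("seasonal summaries find peaks, ties, and the active window", {
  flat <- make_traj(function(doy) rep(5, length(doy)))
  s <- summarize_scenario(flat)
  expect_equal(s$peak, 5)
  expect_equal(s$peak_week, 1L)   # tie broken by earliest week

  tri <- make_traj(function(doy) pmax(0, 100 - abs(doy - 207)))  # week 30 peak
  s_tri <- summarize_scenario(tri)
  expect_equal(s_tri$peak_week, 30L)
  expect_lte(s_tri$onset_week, s_tri$peak_week)
  expect_gte(s_tri$termination_week, s_tri$peak_week)

  g <- glance(s_tri)
  expect_equal(g$peak_week, 30L)
  expect_equal(nrow(tidy(s_tri)), 53L)
})

test_that("multi-year averaging equals a direct per-week oracle", {
  set.seed(9)
  noisy <- make_traj(function(doy) 50 + 20 * sin(2 * pi * doy / 365) +
                       rnorm(length(doy)), years = 2003:2006)
  s <- summarize_scenario(noisy)
  doy <- as.integer(format(noisy$date, "%j"))
  wk <- (doy - 1) %/% 7 + 1
  yr <- as.integer(format(noisy$date, "%Y"))
  oracle <- vapply(sort(unique(wk)), function(w) {
    mean(vapply(2003:2006, function(y) mean(noisy$A[wk == w & yr == y]),
                numeric(1)))
  }, numeric(1))
  expect_equal(s$averaged$mean_adults, oracle)

  # incomplete years are excluded with a warning
  partial <- rbind(noisy, utils::head(make_traj(function(d) d * 0, 2007), 100))
  expect_warning(s2 <- summarize_scenario(partial), "2007")
  expect_equal(s2$averaged$mean_adults, s$averaged$mean_adults)
})

test_that("peak ratios follow the two-decimal comparison convention", {
  flat <- make_traj(function(doy) rep(5, length(doy)))
  s <- summarize_scenario(flat)
  expect_equal(compare_models(s, s), 1.00)
  expect_equal(compare_models(77.6, 57.4), 1.35)
  expect_equal(compare_models(23.7, 21.1), 1.12)
  expect_error(compare_models(5, 0))
})

test_that("bias ratios react to precipitation only through the capacity response", {
  wx <- generate_weather(weather_gen_config(seed = 21), n_years = 3)
  wx_wet <- scenario_shift(wx, precip_scale = 1.2)
  site <- tokyo_site()

  run <- function(weather, nu) {
    env <- build_environment(weather, site)
    p <- model_params(capacity = capacity_params(kappa_max = 100, nu = nu))
    summarize_scenario(simulate_population(env, p), years = 2002:2003)
  }

  # identical inputs: bias exactly 1
  s_base <- run(wx, 1)
  expect_equal(compute_bias(s_base, s_base), 1.00)

  # nu = 1: wetter climate supports a larger peak
  expect_gt(compute_bias(run(wx_wet, 1), s_base), 1)

  # nu = 0: capacity ignores rain entirely, bias exactly 1
  expect_identical(compute_bias(run(wx_wet, 0), run(wx, 0)), 1)

  # bias correction is a plain division
  expect_equal(1.35 / compute_bias(s_base, s_base), 1.35)
})

test_that("driver histograms keep a zero bin and conserve counts", {
  h0 <- driver_histogram(rep(0, 50), "precipitation")
  expect_equal(h0$frequency[h0$bin == "0"], 1)
  expect_equal(sum(h0$count), 50)

  set.seed(2)
  x <- c(rep(0, 30), rgamma(70, 0.8, scale = 12))
  h <- driver_histogram(x, "precipitation", bin_width = 5)
  expect_equal(h$count[1], 30)
  expect_equal(sum(h$count), 100)

  # uniform soil moisture: approximately flat
  set.seed(10)
  u <- runif(1e4, 0, 100)
  hu <- driver_histogram(u, "soil_moisture_ratio", bin_width = 5)
  expect_equal(sum(hu$count), 1e4)
  expect_gt(stats::chisq.test(hu$count)$p.value, 0.01)
})

test_that("uniform climate shifts act only on the intended variables", {
  wx <- test_world()$weather
  expect_identical(scenario_shift(wx, 0, 1), wx)

  shifted <- scenario_shift(wx, 3, 1)
  expect_equal(shifted$t_air, wx$t_air + 3)
  expect_identical(shifted$precip, wx$precip)

  dried <- scenario_shift(wx, 0, 0)
  expect_true(all(dried$precip == 0))
  swb <- soil_water_balance(dried, tokyo_site())
  expect_true(all(diff(swb$soil_water) <= 1e-12))
})
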