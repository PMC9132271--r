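test_that("expected weekly captures average the adult trajectory", {
  dates <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  traj <- tibble::tibble(date = dates, A = 100)
  obs <- tibble::tibble(year = 2003L, week_index = 1:52, count = 1L)
  out <- expected_weekly_capture(traj, obs, 0.01)
  expect_equal(out$lambda, rep(1, 52))

  # zero adults: floored expectation
  traj0 <- tibble::tibble(date = dates, A = 0)
  expect_equal(expected_weekly_capture(traj0, obs, 0.01)$lambda, rep(1e-9, 52))

  # sawtooth adults against a direct loop oracle
  traj_s <- tibble::tibble(date = dates, A = as.numeric(seq_along(dates) %% 11))
  out_s <- expected_weekly_capture(traj_s, obs, 0.02)
  doy <- as.integer(format(dates, "%j"))
  oracle <- vapply(1:52, function(w) {
    0.02 * mean(traj_s$A[doy >= 7 * (w - 1) + 1 & doy <= 7 * w])
  }, numeric(1))
  expect_equal(out_s$lambda, oracle)

  # uncovered week
  obs_far <- tibble::tibble(year = 2004L, week_index = 1L, count = 0L)
  expect_error(expected_weekly_capture(traj, obs_far, 0.01),
               class = "pcmp_coverage_error")
})

test_that("the Poisson log-likelihood matches closed forms and the lgamma oracle", {
  expect_equal(poisson_log_likelihood(0L, 1), -1)
  expect_equal(poisson_log_likelihood(2L, 2), log(2) - 2)

  set.seed(12)
  n <- rpois(40, 3)
  lam <- runif(40, 0.5, 6)
  oracle <- sum(n * log(lam) - lam - lgamma(n + 1))
  expect_equal(poisson_log_likelihood(n, lam), oracle)

  # a shared scalar expectation is maximized at the sample mean
  grid <- seq(0.5, 6, by = 0.001)
  ll_grid <- vapply(grid, function(l) poisson_log_likelihood(n, rep(l, 40)),
                    numeric(1))
  expect_equal(grid[which.max(ll_grid)], mean(n), tolerance = 1e-3)

  expect_error(poisson_log_likelihood(c(1L, -1L), c(1, 1)),
               class = "pcmp_invalid_observation")
})

test_that("per-period likelihoods partition the total", {
  obs <- tibble::tibble(year = rep(2003:2004, each = 52),
                        week_index = rep(1:52, 2))
  set.seed(4)
  obs$count <- rpois(nrow(obs), 2)
  obs$lambda <- runif(nrow(obs), 0.5, 4)

  total <- poisson_log_likelihood(obs$count, obs$lambda)
  all_weeks <- period_log_likelihood(obs, list(all = 1:52))
  expect_equal(all_weeks$mean_log_lik, total / 2)

  parts <- period_log_likelihood(obs, list(a = 1:20, b = 21:52))
  expect_equal(sum(parts$mean_log_lik), total / 2)

  # restricted range against a direct computation
  r <- period_log_likelihood(obs, list(peak = 29:36))
  inside <- obs$week_index %in% 29:36
  expect_equal(r$mean_log_lik,
               poisson_log_likelihood(obs$count[inside], obs$lambda[inside]) / 2)
  expect_error(period_log_likelihood(obs, list(integer(0))))
})

test_that("degenerate annealing schedules behave as specified", {
  world <- test_world()
  gen <- generate_trap_counts(world$weather, trap_gen_config(seed = 2))
  # zero-iteration schedule returns the start
  cfg0 <- calibration_config(free = c("kappa_max", "beta_d1"), n_levels = 0,
                             seed = 1)
  fit0 <- calibrate_model(gen$observations, world$env, model_params(), cfg0)
  expect_equal(fit0$par[["kappa_max"]], 100)
  expect_equal(fit0$par[["beta_d1"]], 14.420)
  expect_equal(nrow(fit0$trace), 0)

  # flat likelihood surface (all counts masked): every proposal accepted
  masked <- gen$observations[0, ]
  cfg_flat <- calibration_config(free = "beta_d1", n_levels = 2,
                                 n_per_level = 30, seed = 1)
  fit_flat <- calibrate_model(masked, world$env, model_params(), cfg_flat)
  expect_equal(mean(fit_flat$trace$accepted), 1)
})

test_that("calibration and validation windows stay disjoint", {
  world <- test_world()
  gen <- generate_trap_counts(world$weather, trap_gen_config(seed = 3))
  calib <- gen$observations[gen$observations$year == 2002, ]
  valid <- gen$observations[gen$observations$year == 2003, ]
  cfg <- calibration_config(free = "kappa_max", n_levels = 2, n_per_level = 10,
                            seed = 1)
  fit <- calibrate_model(calib, world$env, model_params(), cfg)
  expect_equal(fit$n_obs, nrow(calib))   # only the calibration window scored

  # validation likelihood computed on the held-out year with fitted params
  traj <- simulate_population(world$env, fit$params)
  valid_l <- expected_weekly_capture(traj, valid, fit$params$capture_rate)
  per <- period_log_likelihood(valid_l, list(onset = 16:23, peak = 29:36,
                                             termination = 42:49))
  expect_equal(nrow(per), 3)
  expect_true(all(is.finite(per$mean_log_lik)))
})

test_that("calibration is reproducible and its best trace is monotone", {
  world <- test_world()
  gen <- generate_trap_counts(world$weather, trap_gen_config(seed = 5))
  cfg <- calibration_config(free = c("kappa_max", "beta_d1"), n_levels = 4,
                            n_per_level = 25, seed = 7)
  f1 <- calibrate_model(gen$observations, world$env, model_params(), cfg)
  f2 <- calibrate_model(gen$observations, world$env, model_params(), cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  expect_true(all(diff(f1$trace$best_log_lik) >= 0))
  expect_gte(f1$log_lik, f1$trace$log_lik[1])

  td <- tidy(f1)
  expect_equal(td$term, c("kappa_max", "beta_d1"))
  expect_equal(td$transform, c("log10", "identity"))
  g <- glance(f1)
  expect_equal(g$n_proposals, 100)
  expect_true(g$acceptance_rate >= 0 && g$acceptance_rate <= 1)
})
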