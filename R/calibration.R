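#' Expected weekly trap capture
#'
#' The observation model: the expected count in an observation week is the
#' capture rate times the mean daily adult-female abundance over the 7 days
#' of that week.  Captures do not remove individuals from the population.
#' Expectations are floored at 1e-9 so a zero simulated population still has
#' a proper Poisson likelihood.
#'
#' @param trajectory A [simulate_population()] trajectory covering every
#'   observation week.
#' @param observations Trap observations ([read_traps()] format: columns
#'   `year`, `week_index`, `count`).
#' @param capture_rate Fraction of adults captured per trap-week.
#' @return The observations tibble with a `lambda` column appended.
#' @export
expected_weekly_capture <- function(trajectory, observations, capture_rate = 0.01) {
  traj_year <- as.integer(format(trajectory$date, "%Y"))
  traj_week <- week_of_year(trajectory$date)
  key <- paste(traj_year, traj_week)
  mean_a <- tapply(trajectory$A, key, mean)
  obs_key <- paste(observations$year, observations$week_index)
  missing_weeks <- !(obs_key %in% names(mean_a))
  if (any(missing_weeks)) {
    abort(sprintf("trajectory does not cover observation week(s): %s",
                  paste(utils::head(obs_key[missing_weeks], 5), collapse = "; ")),
          class = "pcmp_coverage_error")
  }
  observations$lambda <- pmax(capture_rate * as.numeric(mean_a[obs_key]), 1e-9)
  observations
}

#' Poisson log-likelihood of weekly counts
#'
#' `sum(n * log(lambda) - lambda - log(n!))` over observation weeks, the
#' log-factorial via the log-gamma function.
#'
#' @param counts Nonnegative integer counts.
#' @param lambda Positive expected counts, same length.
#' @return The summed log-likelihood (0 for empty input).
#' @export
poisson_log_likelihood <- function(counts, lambda) {
  if (length(counts) != length(lambda)) {
    abort("`counts` and `lambda` must have the same length.")
  }
  if (length(counts) == 0) return(0)
  if (any(counts < 0 | counts != floor(counts))) {
    abort("counts must be nonnegative integers.", class = "pcmp_invalid_observation")
  }
  if (any(lambda <= 0)) abort("`lambda` must be positive.")
  sum(dpois(counts, lambda, log = TRUE))
}

#' Per-period mean log-likelihood
#'
#' Log-likelihood restricted to observation weeks inside each week range,
#' averaged over the years present.  Used to score model fit separately in
#' the diapause-onset, peak-season, and diapause-termination windows.
#'
#' @param observations Observations with a `lambda` column (see
#'   [expected_weekly_capture()]).
#' @param week_ranges A list of integer vectors of week indices (1--53),
#'   e.g. `list(onset = 16:23, peak = 29:36, termination = 42:49)`.
#' @return A tibble with one row per range: `period`, `weeks`,
#'   `mean_log_lik` (per year), `n_obs`.
#' @export
period_log_likelihood <- function(observations, week_ranges) {
  if (!is.list(week_ranges)) week_ranges <- list(week_ranges)
  if (any(lengths(week_ranges) == 0)) abort("empty week range.")
  if (is.null(names(week_ranges))) {
    names(week_ranges) <- vapply(week_ranges, function(w) {
      sprintf("weeks %d-%d", min(w), max(w))
    }, character(1))
  }
  n_years <- length(unique(observations$year))
  purrr::imap_dfr(week_ranges, function(weeks, nm) {
    if (length(weeks) == 0) abort("empty week range.")
    inside <- observations$week_index %in% weeks
    ll <- poisson_log_likelihood(observations$count[inside],
                                 observations$lambda[inside])
    tibble::tibble(period = nm,
                   weeks = sprintf("%d-%d", min(weeks), max(weeks)),
                   mean_log_lik = ll / n_years,
                   n_obs = sum(inside))
  })
}

#' Calibration configuration
#'
#' Settings for the simulated-annealing Metropolis search.  Parameters named
#' in `free` are searched; `kappa_max` and the four sigmoid slopes move in
#' log10 space, the half-saturation points linearly.  A candidate worse by
#' `delta` is accepted with probability `exp(delta / T)`; the temperature
#' follows a geometric schedule `t_init * cooling^(level - 1)`.
#'
#' @param free Character vector of free parameter names (any of `kappa_max`,
#'   `nu`, `alpha_d1`, `alpha_d2`, `alpha_t1`, `alpha_t2`, `beta_d1`,
#'   `beta_d2`, `beta_t1`, `beta_t2`).
#' @param lower,upper Named bounds on the *transformed* scale (log10 for
#'   `kappa_max`/alphas).  Defaults are generous, except `beta_t1 <= 30`.
#' @param proposal_scale Named random-walk standard deviations on the
#'   transformed scale; defaults 0.1 (log10 units) / 0.1 h / 0.25 degrees C.
#' @param t_init Initial annealing temperature; `NULL` (default) sets it
#'   from probe proposals so that about half of initial worsening moves are
#'   accepted.
#' @param cooling Geometric cooling factor per level, in (0, 1).
#' @param n_per_level Proposals per temperature level.
#' @param n_levels Number of temperature levels.
#' @param seed RNG seed for bit-reproducible searches.
#' @param burn_in_years Leading whole years of the trajectory excluded from
#'   the likelihood.
#' @return A list of class `pcmp_calibration_config`.
#' @export
calibration_config <- function(free = c("kappa_max", "beta_d1", "beta_d2"),
                               lower = NULL, upper = NULL,
                               proposal_scale = NULL,
                               t_init = NULL, cooling = 0.95,
                               n_per_level = 200, n_levels = 60,
                               seed = 1, burn_in_years = 1) {
  default_lower <- c(kappa_max = 0, nu = 0,
                     alpha_d1 = 0, alpha_d2 = 0, alpha_t1 = 0, alpha_t2 = 0,
                     beta_d1 = 8, beta_d2 = 8, beta_t1 = 0, beta_t2 = 0)
  default_upper <- c(kappa_max = 6, nu = 4,
                     alpha_d1 = 6, alpha_d2 = 6, alpha_t1 = 6, alpha_t2 = 6,
                     beta_d1 = 20, beta_d2 = 20, beta_t1 = 30, beta_t2 = 30)
  default_scale <- c(kappa_max = 0.1, nu = 0.1,
                     alpha_d1 = 0.1, alpha_d2 = 0.1, alpha_t1 = 0.1, alpha_t2 = 0.1,
                     beta_d1 = 0.1, beta_d2 = 0.1, beta_t1 = 0.25, beta_t2 = 0.25)
  bad <- setdiff(free, names(default_lower))
  if (length(bad) > 0) {
    abort(sprintf("unknown free parameter(s): %s", paste(bad, collapse = ", ")))
  }
  merge_named <- function(user, def) {
    out <- def[free]
    if (!is.null(user)) out[names(user)] <- user
    out
  }
  lower <- merge_named(lower, default_lower)
  upper <- merge_named(upper, default_upper)
  proposal_scale <- merge_named(proposal_scale, default_scale)
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper),
            cooling > 0, cooling < 1, n_per_level >= 0, n_levels >= 0)
  structure(
    list(free = free, lower = lower, upper = upper,
         proposal_scale = proposal_scale, t_init = t_init, cooling = cooling,
         n_per_level = n_per_level, n_levels = n_levels, seed = seed,
         burn_in_years = burn_in_years),
    class = "pcmp_calibration_config"
  )
}

to_transformed <- function(values, names) {
  vapply(seq_along(names), function(i) {
    if (param_transform_of(names[i]) == "log10") log10(values[i]) else values[i]
  }, numeric(1))
}

from_transformed <- function(theta, names) {
  vals <- vapply(seq_along(names), function(i) {
    if (param_transform_of(names[i]) == "log10") 10^theta[i] else theta[i]
  }, numeric(1))
  names(vals) <- names
  vals
}

#' Fit the model to weekly trap counts by simulated annealing
#'
#' Maximises the Poisson log-likelihood of weekly trap counts over the free
#' parameters with a Metropolis random walk in transformed parameter space
#' under a geometrically cooled temperature schedule.  Candidates outside the
#' bounds are rejected; the best-ever candidate is returned.  Given the same
#' seed, configuration, and data, the result is bit-reproducible.
#'
#' @param observations Trap observations ([read_traps()] format).
#' @param env Environment series from [build_environment()], covering the
#'   burn-in and every observation week.
#' @param params Base [model_params()]; fixed parameters (including the
#'   thermal curves) are taken from here.
#' @param config A [calibration_config()].
#' @param init Initial population state for each model run.
#' @return An object of class `pcmp_fit`: best parameters (natural scale),
#'   best log-likelihood, the full trace, and the updated
#'   [model_params()] at the optimum.  Has [tidy()] and [glance()] methods.
#' @export
calibrate_model <- function(observations, env, params = model_params(),
                            config = calibration_config(),
                            init = initial_state()) {
  free <- config$free
  set.seed(config$seed)

  # burn-in: drop leading whole calendar years from the likelihood
  years <- as.integer(format(env$date, "%Y"))
  drop_years <- utils::head(unique(years), config$burn_in_years)
  obs <- observations[!(observations$year %in% drop_years), , drop = FALSE]

  # thermal rates do not depend on the free parameters: precompute once
  base_rates <- environment_rates(env, params)
  rate_cols <- c("d_E", "d_L", "d_P", "m_E", "m_L", "m_P", "m_A", "o_v")
  fixed_rmat <- as.matrix(base_rates[rate_cols])

  objective <- function(theta) {
    p <- param_set(params, from_transformed(theta, free))
    z1 <- diapause_induction_prob(env$d_week, env$ta_week, env$delta_d, p$diapause)
    z2 <- diapause_termination_prob(env$d_week, env$tw_week, env$delta_d, p$diapause)
    K <- carrying_capacity(env$soil_water, env$w_star, p$capacity)
    rmat <- cbind(fixed_rmat, z1 = z1, z2 = z2, K = K)
    states <- rk4_core(as.numeric(init)[1:5], rmat, 1L)
    if (nrow(obs) == 0) return(0)
    traj <- tibble::tibble(date = env$date, A = states[, 5])
    obs_l <- expected_weekly_capture(traj, obs, params$capture_rate)
    poisson_log_likelihood(obs_l$count, obs_l$lambda)
  }

  theta <- to_transformed(vapply(free, function(nm) param_get(params, nm),
                                 numeric(1)), free)
  names(theta) <- free
  if (any(theta < config$lower | theta > config$upper)) {
    abort("starting parameters lie outside the search bounds.")
  }
  ll <- objective(theta)
  best_theta <- theta
  best_ll <- ll

  n_prop <- config$n_levels * config$n_per_level
  trace <- list(iteration = integer(n_prop), level = integer(n_prop),
                temperature = numeric(n_prop), log_lik = numeric(n_prop),
                best_log_lik = numeric(n_prop), accepted = logical(n_prop))

  # auto initial temperature: median worsening of a few probe moves,
  # scaled so the median worsening is accepted with probability ~1/2
  t_init <- config$t_init
  if (is.null(t_init) && n_prop > 0) {
    drops <- replicate(20, {
      cand <- theta + rnorm(length(free), 0, config$proposal_scale)
      if (any(cand < config$lower | cand > config$upper)) NA_real_
      else max(ll - objective(cand), 0)
    })
    med <- median(drops, na.rm = TRUE)
    t_init <- if (!is.finite(med) || med <= 0) 1 else med / log(2)
  }
  if (is.null(t_init)) t_init <- 1

  it <- 0L
  for (level in seq_len(config$n_levels)) {
    temp <- t_init * config$cooling^(level - 1)
    n_acc_level <- 0L
    for (j in seq_len(config$n_per_level)) {
      it <- it + 1L
      cand <- theta + rnorm(length(free), 0, config$proposal_scale)
      acc <- FALSE
      if (all(cand >= config$lower & cand <= config$upper)) {
        cand_ll <- objective(cand)
        if (runif(1) < exp(min((cand_ll - ll) / temp, 0))) {
          theta <- cand
          ll <- cand_ll
          acc <- TRUE
          if (ll > best_ll) {
            best_ll <- ll
            best_theta <- theta
          }
        }
      }
      n_acc_level <- n_acc_level + acc
      trace$iteration[it] <- it
      trace$level[it] <- level
      trace$temperature[it] <- temp
      trace$log_lik[it] <- ll
      trace$best_log_lik[it] <- best_ll
      trace$accepted[it] <- acc
    }
    if (level == 1 && config$n_per_level >= 20 && n_acc_level == 0) {
      abort(paste("every proposal at the initial temperature was rejected;",
                  "reduce `proposal_scale` or raise `t_init`."),
            class = "pcmp_calibration_stuck")
    }
  }

  best <- from_transformed(best_theta, free)
  structure(
    list(par = best, log_lik = best_ll,
         params = param_set(params, best),
         trace = tibble::as_tibble(trace),
         start = from_transformed(to_transformed(vapply(free, function(nm) {
           param_get(params, nm)
         }, numeric(1)), free), free),
         config = config, seed = config$seed, n_obs = nrow(obs)),
    class = "pcmp_fit"
  )
}

#' @export
print.pcmp_fit <- function(x, ...) {
  cat("<pcmp_fit> simulated-annealing calibration\n")
  cat(sprintf("  log-likelihood: %.3f over %d observations\n", x$log_lik, x$n_obs))
  for (nm in names(x$par)) cat(sprintf("  %-10s %g\n", nm, x$par[[nm]]))
  invisible(x)
}
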