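#' Larval carrying capacity from soil moisture
#'
#' `K = kappa_max * (W / W*)^nu`.  With `nu = 0` the capacity is fixed at
#' `kappa_max`; with `nu > 0` it grows monotonically with soil moisture,
#' reaching `kappa_max` at saturation.  A tiny positive floor (1e-6) is kept
#' when the soil is completely dry so the larval crowding term `L / K`
#' remains finite (biologically, a dry-soil refuge of negligible size).
#'
#' @param soil_water Soil water content `W` (mm), in `[0, w_star]`.
#' @param w_star Soil water-holding capacity (mm), > 0.
#' @param params A [capacity_params()].
#' @return Carrying capacity in individuals, vectorised over `soil_water`.
#' @examples
#' carrying_capacity(37.5, 150, capacity_params(kappa_max = 100, nu = 0.5))
#' @export
carrying_capacity <- function(soil_water, w_star, params = capacity_params()) {
  if (any(w_star <= 0)) abort("`w_star` must be > 0.", class = "pcmp_invalid_site")
  if (any(soil_water < 0 | soil_water > w_star + 1e-9)) {
    abort("soil water must lie in [0, w_star].", class = "pcmp_invariant_violation")
  }
  ratio <- pmin(pmax(soil_water / w_star, 0), 1)
  k <- params$kappa_max * ratio^params$nu   # 0^0 == 1: nu = 0 gives kappa_max
  pmax(k, 1e-6)
}

# logistic 1 / (1 + exp(-u)), saturating exactly to 0/1 for |u| > 700 so that
# the extreme fitted slopes (up to 10^5.1) can never overflow.
stable_sigmoid <- function(u) {
  1 / (1 + exp(pmin(pmax(-u, -700), 700)))
}

#' Diapause induction probability (z1)
#'
#' Probability that a newly laid egg enters diapause.  Defined only while
#' days shorten (`delta_d < 0`); otherwise exactly 0.  On shortening days it
#' is the product of two sigmoids: one rising as weekly mean photoperiod
#' falls below `beta_d1`, one rising as weekly mean air temperature falls
#' below `beta_t1`.
#'
#' @param d_week Trailing 7-day mean photoperiod (h).
#' @param ta_week Trailing 7-day mean air temperature (degrees C).
#' @param delta_d Day-to-day change in photoperiod (h/day).
#' @param params A [diapause_params()].
#' @return Probabilities in `[0, 1]`, vectorised.
#' @export
diapause_induction_prob <- function(d_week, ta_week, delta_d,
                                    params = diapause_params()) {
  z <- stable_sigmoid(params$alpha_d1 * (params$beta_d1 - d_week)) *
    stable_sigmoid(params$alpha_t1 * (params$beta_t1 - ta_week))
  z[delta_d >= 0] <- 0
  z
}

#' Diapause termination probability (z2)
#'
#' Daily probability that a diapausing egg resumes development.  Defined only
#' while days lengthen (`delta_d > 0`); otherwise exactly 0.  On lengthening
#' days it is the product of a sigmoid rising as weekly mean photoperiod
#' exceeds `beta_d2` and one rising as weekly mean *water* temperature
#' exceeds `beta_t2` (the egg sits at the waterline, so the breaking cue is
#' the aquatic-habitat temperature).
#'
#' @param d_week Trailing 7-day mean photoperiod (h).
#' @param tw_week Trailing 7-day mean water temperature (degrees C).
#' @inheritParams diapause_induction_prob
#' @return Probabilities in `[0, 1]`, vectorised.
#' @export
diapause_termination_prob <- function(d_week, tw_week, delta_d,
                                      params = diapause_params()) {
  z <- stable_sigmoid(params$alpha_d2 * (d_week - params$beta_d2)) *
    stable_sigmoid(params$alpha_t2 * (tw_week - params$beta_t2))
  z[delta_d <= 0] <- 0
  z
}

#' Hard-threshold diapause switches
#'
#' An alternative on/off diapause rule using fixed weekly-mean cut-offs
#' instead of sigmoids: diapause is induced when both the weekly mean air
#' temperature and photoperiod fall below their thresholds, and broken when
#' both exceed theirs.  Defaults follow the published rule for this species:
#' induction below 21 degrees C and 13.5 h, breaking above 10.5 degrees C and
#' 10.25 h.  The flags can substitute for `z1`/`z2` as 0/1 probabilities.
#'
#' @param ta_week Trailing 7-day mean air temperature (degrees C).
#' @param d_week Trailing 7-day mean photoperiod (h).
#' @param t_on,d_on Induction thresholds (strict `<`).
#' @param t_off,d_off Breaking thresholds (strict `>`).
#' @return A tibble with logical columns `diapause_on`, `break_on`.
#' @export
threshold_diapause <- function(ta_week, d_week, t_on = 21, d_on = 13.5,
                               t_off = 10.5, d_off = 10.25) {
  tibble::tibble(
    diapause_on = ta_week < t_on & d_week < d_on,
    break_on = ta_week > t_off & d_week > d_off
  )
}

#' Stage rates for each day of an environment series
#'
#' Evaluates every temperature-dependent vital rate, the diapause
#' probabilities, and the carrying capacity on each day of a derived
#' environment series.  Aquatic-stage rates use water temperature, adult
#' mortality and oviposition use air temperature.
#'
#' @param env Environment tibble from [build_environment()].
#' @param params A [model_params()].
#' @return A tibble with columns `d_E`, `d_L`, `d_P`, `m_E`, `m_L`, `m_P`,
#'   `m_A`, `o_v`, `z1`, `z2`, `K`.
#' @export
environment_rates <- function(env, params = model_params()) {
  th <- params$thermal
  tw <- env$t_water
  ta <- env$t_air
  tibble::tibble(
    d_E = thermal_rate(th$d_E, tw),
    d_L = thermal_rate(th$d_L, tw),
    d_P = thermal_rate(th$d_P, tw),
    m_E = thermal_rate(th$m_E, tw),
    m_L = thermal_rate(th$m_L, tw),
    m_P = thermal_rate(th$m_P, tw),
    m_A = thermal_rate(th$m_A, ta),
    o_v = thermal_rate(th$o_v, ta),
    z1 = diapause_induction_prob(env$d_week, env$ta_week, env$delta_d,
                                 params$diapause),
    z2 = diapause_termination_prob(env$d_week, env$tw_week, env$delta_d,
                                   params$diapause),
    K = carrying_capacity(env$soil_water, env$w_star, params$capacity)
  )
}

#' Instantaneous rates of change of the five stages
#'
#' The right-hand side of the stage-structured system: oviposition splits
#' into active and diapausing eggs by `z1`, diapausing eggs re-enter the
#' active egg pool at rate `z2`, larvae suffer density-dependent crowding
#' mortality `L / K`, and each aquatic stage matures into the next at its
#' development rate.
#'
#' @param state A [initial_state()]-style named vector `(E, E_dia, L, P, A)`.
#' @param rates A single day's rates: one row of [environment_rates()] or an
#'   equivalent named list.
#' @return Named numeric vector of derivatives (per day).
#' @export
stage_derivatives <- function(state, rates) {
  if (any(!is.finite(unlist(state))) || any(unlist(state) < 0)) {
    abort("state must be finite and nonnegative.", class = "pcmp_invalid_state")
  }
  if (rates$K <= 0) abort("carrying capacity must be > 0.", class = "pcmp_invalid_capacity")
  E <- state[["E"]]; E_dia <- state[["E_dia"]]; L <- state[["L"]]
  P <- state[["P"]]; A <- state[["A"]]
  with(as.list(rates), c(
    E = (1 - z1) * o_v * A - (m_E + d_E) * E + z2 * E_dia,
    E_dia = z1 * o_v * A - z2 * E_dia,
    L = d_E * E - (m_L + d_L + L / K) * L,
    P = d_L * L - (m_P + d_P) * P,
    A = d_P * P - m_A * A
  ))
}

#' Advance the population by one day
#'
#' One explicit 4th-order Runge--Kutta day step with the day's environment
#' held constant.  `substeps` subdivides the day for convergence checks;
#' components are clamped at zero after each sub-step.
#'
#' @param state Named state vector `(E, E_dia, L, P, A)`.
#' @param rates One day's rates (one row of [environment_rates()]).
#' @param substeps Number of equal sub-steps within the day (`dt = 1/substeps`).
#' @return The state at the end of the day, as a named vector.
#' @export
step_population <- function(state, rates, substeps = 1L) {
  stopifnot(substeps >= 1)
  rmat <- matrix(unlist(rates[c("d_E", "d_L", "d_P", "m_E", "m_L", "m_P",
                                "m_A", "o_v", "z1", "z2", "K")]),
                 nrow = 1)
  out <- rk4_core(as.numeric(state)[1:5], rmat, as.integer(substeps))
  s <- drop(out)
  names(s) <- c("E", "E_dia", "L", "P", "A")
  s
}

#' Simulate the population over an environment series
#'
#' Integrates the five-stage system day by day over a derived environment
#' series with a daily 4th-order Runge--Kutta step (each day's drivers held
#' constant within the day).  Deterministic given its inputs.
#'
#' @param env Environment tibble from [build_environment()].
#' @param params A [model_params()].
#' @param init Initial state, default [initial_state()] (overwintering
#'   diapausing eggs on January 1).
#' @param substeps Sub-steps per day for the integrator (default 1).
#' @return A tibble of class `pcmp_trajectory` with one row per day: `date`,
#'   the five stage abundances, and the day's `K`, `z1`, `z2`.  Row `t` is
#'   the state at the end of day `t`.
#' @examples
#' wx <- generate_weather(weather_gen_config(seed = 1), n_years = 2)
#' env <- build_environment(wx, tokyo_site())
#' traj <- simulate_population(env, model_params())
#' @export
simulate_population <- function(env, params = model_params(),
                                init = initial_state(), substeps = 1L) {
  rates <- environment_rates(env, params)
  rmat <- as.matrix(rates[c("d_E", "d_L", "d_P", "m_E", "m_L", "m_P",
                            "m_A", "o_v", "z1", "z2", "K")])
  states <- rk4_core(as.numeric(init)[1:5], rmat, as.integer(substeps))
  out <- tibble::tibble(
    date = env$date,
    E = states[, 1], E_dia = states[, 2], L = states[, 3],
    P = states[, 4], A = states[, 5],
    K = rates$K, z1 = rates$z1, z2 = rates$z2
  )
  class(out) <- c("pcmp_trajectory", class(out))
  out
}
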