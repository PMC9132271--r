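#' Diapause sigmoid parameters
#'
#' Slopes and half-saturation points of the four sigmoids controlling egg
#' diapause.  Induction (the probability `z1` that a newly laid egg enters
#' diapause, active only while days shorten) is a product of a photoperiod
#' sigmoid — rising as the weekly mean daylength falls below `beta_d1` — and
#' an air-temperature sigmoid rising as the weekly mean air temperature falls
#' below `beta_t1`.  Termination (`z2`, active only while days lengthen)
#' rises as weekly daylength exceeds `beta_d2` and weekly *water* temperature
#' exceeds `beta_t2`.
#'
#' Defaults are the Tokyo estimates for the rainfall-responsive model
#' (capacity responsiveness `nu = 1`): very steep photoperiod gates near
#' 14.4 h (induction) and 11.5 h (termination), with temperature gates near
#' 28.8 degrees C and 9.5 degrees C.
#'
#' @param alpha_d1,alpha_d2 Photoperiod sigmoid slopes (per hour), > 0.
#' @param alpha_t1,alpha_t2 Temperature sigmoid slopes (per degree C), > 0.
#' @param beta_d1,beta_d2 Photoperiod half-saturation points (hours, 0--24).
#' @param beta_t1,beta_t2 Temperature half-saturation points (degrees C).
#' @return A list of class `pcmp_diapause_params`.
#' @export
diapause_params <- function(alpha_d1 = 10^5.10, alpha_d2 = 10^3.84,
                            alpha_t1 = 10^4.70, alpha_t2 = 10^2.42,
                            beta_d1 = 14.420, beta_d2 = 11.518,
                            beta_t1 = 28.822, beta_t2 = 9.458) {
  p <- list(alpha_d1 = alpha_d1, alpha_d2 = alpha_d2,
            alpha_t1 = alpha_t1, alpha_t2 = alpha_t2,
            beta_d1 = beta_d1, beta_d2 = beta_d2,
            beta_t1 = beta_t1, beta_t2 = beta_t2)
  if (any(unlist(p[1:4]) <= 0)) {
    abort("all sigmoid slopes (alpha) must be > 0.", class = "pcmp_invalid_params")
  }
  if (beta_d1 <= 0 || beta_d1 >= 24 || beta_d2 <= 0 || beta_d2 >= 24) {
    abort("photoperiod half-saturation points must lie in (0, 24) h.",
          class = "pcmp_invalid_params")
  }
  if (beta_t1 < 0 || beta_t1 > 40 || beta_t2 < 0 || beta_t2 > 40) {
    abort("temperature half-saturation points must lie in [0, 40] C.",
          class = "pcmp_invalid_params")
  }
  structure(p, class = "pcmp_diapause_params")
}

#' Larval carrying-capacity parameters
#'
#' The larval carrying capacity is `K = kappa_max * (W / W*)^nu`: the maximum
#' capacity scaled by the soil moisture ratio raised to the responsiveness
#' exponent.  `nu = 0` fixes the capacity at `kappa_max` regardless of
#' rainfall; `nu = 1` makes it proportional to soil moisture.
#'
#' @param kappa_max Maximum larval carrying capacity (individuals), > 0.
#'   Default 100, the Tokyo estimate for the `nu = 1` model.
#' @param nu Responsiveness of capacity to soil moisture, >= 0.
#' @return A list of class `pcmp_capacity_params`.
#' @export
capacity_params <- function(kappa_max = 100, nu = 1) {
  if (kappa_max <= 0) abort("`kappa_max` must be > 0.", class = "pcmp_invalid_params")
  if (nu < 0) abort("`nu` must be >= 0.", class = "pcmp_invalid_params")
  structure(list(kappa_max = kappa_max, nu = nu), class = "pcmp_capacity_params")
}

#' Full population-model parameter set
#'
#' @param diapause A [diapause_params()].
#' @param capacity A [capacity_params()].
#' @param thermal A [thermal_response_set()].
#' @param capture_rate Fraction of active adults captured per trap per week,
#'   in (0, 1]; default 0.01 (1 % of active adults captured).
#' @return A list of class `pcmp_model_params`.
#' @export
model_params <- function(diapause = diapause_params(),
                         capacity = capacity_params(),
                         thermal = thermal_response_set(),
                         capture_rate = 0.01) {
  stopifnot(inherits(diapause, "pcmp_diapause_params"),
            inherits(capacity, "pcmp_capacity_params"),
            inherits(thermal, "pcmp_thermal_set"))
  if (capture_rate <= 0 || capture_rate > 1) {
    abort("`capture_rate` must be in (0, 1].", class = "pcmp_invalid_params")
  }
  structure(list(diapause = diapause, capacity = capacity, thermal = thermal,
                 capture_rate = capture_rate),
            class = "pcmp_model_params")
}

#' Initial population state
#'
#' The simulation convention is a January 1 start with the whole population
#' overwintering as diapausing eggs; a burn-in year is discarded before any
#' likelihood or summary so results are insensitive to the arbitrary start.
#'
#' @param E,E_dia,L,P,A Stage abundances (nonnegative): active eggs,
#'   diapausing eggs, larvae, pupae, adult females.
#' @return A named numeric vector of class `pcmp_state`.
#' @export
initial_state <- function(E = 0, E_dia = 1000, L = 0, P = 0, A = 0) {
  s <- c(E = E, E_dia = E_dia, L = L, P = P, A = A)
  if (any(!is.finite(s)) || any(s < 0)) {
    abort("all stage abundances must be finite and >= 0.",
          class = "pcmp_invalid_state")
  }
  structure(s, class = "pcmp_state")
}

# Named access into the flat calibration parameter space.
# kappa_max and the four alphas are searched in log10; betas linearly.
param_get <- function(params, name) {
  switch(name,
    kappa_max = params$capacity$kappa_max,
    nu = params$capacity$nu,
    params$diapause[[name]]
  )
}

param_set <- function(params, theta) {
  for (name in names(theta)) {
    val <- theta[[name]]
    if (name == "kappa_max") params$capacity$kappa_max <- val
    else if (name == "nu") params$capacity$nu <- val
    else if (name %in% names(params$diapause)) params$diapause[[name]] <- val
    else abort(sprintf("unknown free parameter '%s'", name))
  }
  params
}

param_transform_of <- function(name) {
  if (name %in% c("kappa_max", "alpha_d1", "alpha_d2", "alpha_t1", "alpha_t2")) {
    "log10"
  } else {
    "identity"
  }
}
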