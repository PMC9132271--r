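#' Thermal-response curves
#'
#' Parametric temperature-response curves for the stage-specific rates of the
#' population model.  Three shapes cover the standard forms used for insect
#' vital rates:
#'
#' * `"briere"` — Briere-1, `a * T * (T - t_min) * sqrt(t_max - T)` inside
#'   `(t_min, t_max)`, 0 outside: the usual left-skewed unimodal shape for
#'   development and oviposition rates.
#' * `"quadratic"` — `a * (T - t_min) * (t_max - T)` inside the range, 0
#'   outside: a symmetric unimodal alternative.
#' * `"ushape"` — `m_min + a * (T - t_opt)^2`: mortality, lowest at the
#'   thermal optimum and rising toward both cold and heat, with a strictly
#'   positive floor `m_min`.
#'
#' @param shape One of `"briere"`, `"quadratic"`, `"ushape"`.
#' @param pars Named numeric vector of curve parameters: `a`, `t_min`,
#'   `t_max` for the unimodal shapes; `m_min`, `a`, `t_opt` for `"ushape"`.
#' @return A `pcmp_thermal_curve` object.
#' @seealso [thermal_rate()], [thermal_response_set()]
#' @export
thermal_curve <- function(shape = c("briere", "quadratic", "ushape"), pars) {
  shape <- match.arg(shape)
  needed <- switch(shape,
    briere = c("a", "t_min", "t_max"),
    quadratic = c("a", "t_min", "t_max"),
    ushape = c("m_min", "a", "t_opt")
  )
  if (!all(needed %in% names(pars))) {
    abort(sprintf("curve shape '%s' needs parameters: %s", shape,
                  paste(needed, collapse = ", ")))
  }
  if (shape == "ushape" && pars[["m_min"]] <= 0) {
    abort("mortality floor `m_min` must be > 0.")
  }
  structure(list(shape = shape, pars = as.list(pars)),
            class = "pcmp_thermal_curve")
}

#' Evaluate a thermal-response curve
#'
#' @param curve A [thermal_curve()].
#' @param temp Temperature(s), degrees C.
#' @return Nonnegative rate(s), per day (oviposition: eggs per female per day).
#' @export
thermal_rate <- function(curve, temp) {
  p <- curve$pars
  switch(curve$shape,
    briere = {
      inside <- temp > p$t_min & temp < p$t_max
      r <- numeric(length(temp))
      tt <- temp[inside]
      r[inside] <- p$a * tt * (tt - p$t_min) * sqrt(p$t_max - tt)
      pmax(r, 0)
    },
    quadratic = {
      inside <- temp > p$t_min & temp < p$t_max
      r <- numeric(length(temp))
      tt <- temp[inside]
      r[inside] <- p$a * (tt - p$t_min) * (p$t_max - tt)
      pmax(r, 0)
    },
    ushape = p$m_min + p$a * (temp - p$t_opt)^2
  )
}

#' Default set of thermal-response curves
#'
#' The full set of temperature-dependent vital rates: development rates
#' `d_E`, `d_L`, `d_P` and mortality rates `m_E`, `m_L`, `m_P` for the
#' aquatic stages (driven by water temperature), adult mortality `m_A` and
#' the per-female oviposition rate `o_v` (driven by air temperature).
#'
#' The shipped parameter values are literature-informed defaults for a
#' temperate *Aedes albopictus* population: egg-to-hatch ~10 days, larval
#' duration ~8 days and pupal duration ~3 days near 25 degrees C inside a
#' roughly 10--38 degrees C activity window; mortality minima of 1--3 %/day
#' at the thermal optimum rising quadratically toward cold and heat; and an
#' oviposition rate peaking around 3 eggs/female/day in the low 30s.  Every
#' curve is overridable.
#'
#' @param ... Named replacements for any of `d_E`, `d_L`, `d_P`, `m_E`,
#'   `m_L`, `m_P`, `m_A`, `o_v`, each a [thermal_curve()].
#' @return A named list of class `pcmp_thermal_set`.
#' @export
thermal_response_set <- function(...) {
  set <- list(
    d_E = thermal_curve("briere", c(a = 7.5e-5, t_min = 10, t_max = 38)),
    d_L = thermal_curve("briere", c(a = 9.0e-5, t_min = 10, t_max = 38)),
    d_P = thermal_curve("briere", c(a = 2.6e-4, t_min = 10, t_max = 38)),
    m_E = thermal_curve("ushape", c(m_min = 0.010, a = 2.0e-4, t_opt = 25)),
    m_L = thermal_curve("ushape", c(m_min = 0.020, a = 3.0e-4, t_opt = 25)),
    m_P = thermal_curve("ushape", c(m_min = 0.020, a = 3.0e-4, t_opt = 25)),
    m_A = thermal_curve("ushape", c(m_min = 0.030, a = 5.0e-4, t_opt = 22)),
    o_v = thermal_curve("briere", c(a = 2.8e-3, t_min = 14, t_max = 40))
  )
  override <- list(...)
  if (length(override) > 0) {
    bad <- setdiff(names(override), names(set))
    if (length(bad) > 0) {
      abort(sprintf("unknown thermal curve(s): %s", paste(bad, collapse = ", ")))
    }
    ok <- vapply(override, inherits, logical(1), "pcmp_thermal_curve")
    if (!all(ok)) abort("replacements must be thermal_curve objects.")
    set[names(override)] <- override
  }
  structure(set, class = "pcmp_thermal_set")
}
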