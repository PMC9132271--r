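#' Tidy a calibration fit
#'
#' One row per free parameter: the estimate on the natural scale, the search
#' transform, and the starting value.
#'
#' @param x A `pcmp_fit` from [calibrate_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `transform`, `start`.
#' @method tidy pcmp_fit
#' @export
tidy.pcmp_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par),
    transform = unname(vapply(names(x$par), param_transform_of, character(1))),
    start = unname(x$start[names(x$par)])
  )
}

#' One-line summary of a calibration fit
#'
#' @inheritParams tidy.pcmp_fit
#' @return A one-row tibble: `log_lik`, `n_obs`, `n_proposals`,
#'   `acceptance_rate`, `seed`.
#' @method glance pcmp_fit
#' @export
glance.pcmp_fit <- function(x, ...) {
  tibble::tibble(
    log_lik = x$log_lik,
    n_obs = x$n_obs,
    n_proposals = nrow(x$trace),
    acceptance_rate = if (nrow(x$trace) > 0) mean(x$trace$accepted) else NA_real_,
    seed = x$seed
  )
}

#' Tidy a scenario summary
#'
#' @param x A `pcmp_summary` from [summarize_scenario()].
#' @param ... Unused.
#' @return The averaged weekly dynamics: a tibble with `week`, `mean_adults`.
#' @method tidy pcmp_summary
#' @export
tidy.pcmp_summary <- function(x, ...) {
  x$averaged
}

#' One-line summary of a scenario
#'
#' @inheritParams tidy.pcmp_summary
#' @return A one-row tibble: `peak`, `peak_week`, `onset_week`,
#'   `termination_week`, `n_years`.
#' @method glance pcmp_summary
#' @export
glance.pcmp_summary <- function(x, ...) {
  tibble::tibble(
    peak = x$peak,
    peak_week = x$peak_week,
    onset_week = x$onset_week,
    termination_week = x$termination_week,
    n_years = length(x$years)
  )
}
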