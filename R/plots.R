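#' Plot a simulated trajectory
#'
#' Daily abundances of the five life stages on a log-friendly free scale,
#' one facet per stage.
#'
#' @param object A `pcmp_trajectory` from [simulate_population()].
#' @param stages Stages to draw (default all five).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcmp_trajectory
#' @export
autoplot.pcmp_trajectory <- function(object, stages = c("E", "E_dia", "L", "P", "A"),
                                     ...) {
  long <- object |>
    dplyr::select(dplyr::all_of(c("date", stages))) |>
    tidyr::pivot_longer(-"date", names_to = "stage", values_to = "abundance") |>
    dplyr::mutate(stage = factor(.data$stage, levels = stages))
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$abundance)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~stage, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = "abundance",
                  title = "Simulated stage dynamics") +
    ggplot2::theme_minimal()
}

#' Plot averaged weekly seasonal dynamics
#'
#' Per-year weekly mean adults as light lines with the cross-year average on
#' top, plus the peak week and the active-season window.
#'
#' @param object A `pcmp_summary` from [summarize_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcmp_summary
#' @export
autoplot.pcmp_summary <- function(object, ...) {
  ggplot2::ggplot(object$averaged, ggplot2::aes(.data$week, .data$mean_adults)) +
    ggplot2::geom_line(
      data = object$weekly,
      ggplot2::aes(group = .data$year), colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_line(colour = "#d7301f", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$peak_week, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::annotate("rect",
                      xmin = object$onset_week, xmax = object$termination_week,
                      ymin = -Inf, ymax = Inf, alpha = 0.06, fill = "#d7301f") +
    ggplot2::labs(x = "week of year", y = "weekly mean adult females",
                  title = "Averaged seasonal dynamics",
                  subtitle = sprintf("peak %.1f at week %d; active weeks %d-%d",
                                     object$peak, object$peak_week,
                                     object$onset_week, object$termination_week)) +
    ggplot2::theme_minimal()
}

#' Plot a driver frequency histogram
#'
#' @param histogram A tibble from [driver_histogram()].
#' @return A ggplot object.
#' @export
plot_driver_histogram <- function(histogram) {
  histogram$bin <- factor(histogram$bin, levels = histogram$bin)
  ggplot2::ggplot(histogram, ggplot2::aes(.data$bin, .data$frequency)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
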