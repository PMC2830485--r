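#' Plot a simulated time course
#'
#' Total cell numbers per compartment against time, on a log10 count scale
#' (zero counts are floored at one cell for display).
#'
#' @param object A `bk_timecourse` from [integrate_model()].
#' @param compartments Compartments to show (default splenic subsets).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bk_timecourse <- function(object, compartments = splenic_subsets(),
                                   ...) {
  df <- object |>
    filter(.data$compartment %in% compartments) |>
    mutate(total = pmax(.data$total, 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_days, y = .data$total,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "cells", colour = "subset")
}

#' Plot BrdU labeling kinetics
#'
#' Labeled-cell numbers per subset against time since labeling start.
#'
#' @param object A `bk_labeled_timecourse` from [simulate_brdu()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bk_labeled_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_days, y = .data$labeled,
                                       colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "days of labeling", y = "BrdU-labeled cells",
                  colour = "subset")
}

#' Plot a fit against the data
#'
#' The best-fit simulated labeling curves overlaid on the observed
#' labeled-cell numbers (one point per mouse).
#'
#' @param object A `bk_fit` from [grid_search()].
#' @param data The dataset the fit was run on.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bk_fit <- function(object, data, ...) {
  if (is.null(object$best)) {
    abort("empty feasible set: nothing to plot", class = "bk_invalid_argument")
  }
  sim <- simulate_brdu(object$bm, object$best, object$topo,
                       sample_days = object$sample_days,
                       schedule = object$schedule, dt = object$dt,
                       subsets = object$subsets)
  obs <- data |> filter(.data$subset %in% object$subsets)
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$time_days, colour = .data$subset)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$labeled)) +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(y = .data$labeled_count), alpha = 0.6) +
    ggplot2::labs(x = "days of labeling", y = "BrdU-labeled cells",
                  colour = "subset")
}

#' Plot the mature-to-T3 recursion flux over time
#'
#' @param flux A tibble from [flux_series()].
#' @return A ggplot object.
#' @export
plot_flux_series <- function(flux) {
  ggplot2::ggplot(flux, ggplot2::aes(x = .data$time_days, y = .data$flux)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)",
                  y = "mature-to-T3 flux (cells per 6 h)")
}
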