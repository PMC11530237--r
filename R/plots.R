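# ggplot2 methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitness landscape
#'
#' Isoclines of the Malthusian parameter for both lineages over the
#' trait plane, with the `x_b = x_d` diagonal. Above the diagonal the
#' two sets of isoclines overlap; below it the Lansing isoclines bunch
#' together -- the stronger Lansing fitness gradient.
#'
#' @param object A `bd_landscape` from [fitness_landscape()].
#' @param bins Number of contour bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bd_landscape
#' @export
autoplot.bd_landscape <- function(object, bins = 10, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("lambda_non_lansing", "lambda_lansing"),
    names_to = "lineage", names_prefix = "lambda_",
    values_to = "lambda")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$x_b, .data$x_d, z = .data$lambda,
                               colour = .data$lineage)) +
    ggplot2::geom_contour(bins = bins) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         colour = "darkgreen", linetype = 2) +
    ggplot2::labs(x = "fertility span end x_b",
                  y = "mortality onset x_d",
                  colour = NULL,
                  title = "Malthusian fitness isoclines") +
    ggplot2::theme_minimal()
}

#' @rdname gap_landscape
#' @param object A `bd_gap_landscape`.
#' @param ... Unused.
#' @method autoplot bd_gap_landscape
#' @export
autoplot.bd_gap_landscape <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$i_b, .data$i_d, fill = .data$gap)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "birth intensity i_b", y = "death intensity i_d",
                  fill = "gap",
                  title = "Asymptotic fertility-mortality gap") +
    ggplot2::theme_minimal()
}

#' @rdname integrate_canonical
#' @param object A `bd_trajectory`.
#' @method autoplot bd_trajectory
#' @export
autoplot.bd_trajectory <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "gap_predicted"),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "arc length along the canonical trajectory",
                  y = "x_b - x_d",
                  title = "Canonical trait dynamics of the gap") +
    ggplot2::theme_minimal()
}

#' @rdname simulate_bd
#' @param object A `bd_sim` with a recorded event log.
#' @method autoplot bd_sim
#' @export
autoplot.bd_sim <- function(object, ...) {
  tr <- population_trajectory(object)
  ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$n,
                                   colour = .data$lineage)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "living individuals", colour = NULL,
                  title = "Population size by lineage") +
    ggplot2::theme_minimal()
}

#' @rdname summarize_deciles
#' @param object A `bd_deciles`.
#' @param ... Unused.
#' @method autoplot bd_deciles
#' @export
autoplot.bd_deciles <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$d5,
                               colour = .data$lineage,
                               fill = .data$lineage)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$d1, ymax = .data$d9),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time",
                  y = paste0(attr(object, "statistic"),
                             " (deciles 1, 5, 9)"),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
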