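# ggplot2 autoplot methods for the package's result objects.

#' Plot a voltage trace
#'
#' Somatic membrane potential against time as a line plot.
#'
#' @param object A `voltage_trace` tibble (from [simulate_cell()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voltage_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$v_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a simulation grid
#'
#' Firing category of every basal x apical combination as a tile map;
#' failed combinations are shown as blank tiles.
#'
#' @param object A `grid_result` (from [run_grid()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$apical_id, y = .data$basal_id,
                                  fill = .data$category)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(
      values = c(RS = "#2166ac", IB = "#b2182b", Q = "grey70"),
      na.value = "white", name = "category") +
    ggplot2::labs(x = "apical donor", y = "basal donor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a classifier report
#'
#' Per-repeat sensitivity, specificity and accuracy with the mean of each
#' metric overlaid.
#'
#' @param object A `classifier_report` (from [bayes_evaluate()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$repeats,
                           c("sensitivity", "specificity", "accuracy"),
                           names_to = "metric", values_to = "value")
  means <- d |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(value = mean(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::geom_point(data = means, color = "#b2182b", size = 3,
                        shape = 18) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "fraction",
                  subtitle = sprintf("%d repeats, positive class IB",
                                     nrow(object$repeats))) +
    ggplot2::theme_minimal()
}
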