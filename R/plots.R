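# ggplot2 displays for the result types.

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "predicted", y = "actual", fill = "count") +
    ggplot2::theme_minimal()
}

#' Per-class recall / precision / F-measure bars
#'
#' @param object A `classification_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classification_metrics <- function(object, ...) {
  d <- tidyr::pivot_longer(object$by_class,
                           c("recall", "precision", "f_measure"),
                           names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Granulometric size-distribution curves
#'
#' @param curves A single [granulometry_curve()] vector or a named list of
#'   them (e.g. one per image).
#' @param sizes Structuring-element diameters matching the curve values.
#' @return A ggplot of `F_B` against element size.
#' @export
plot_granulometry <- function(curves, sizes = granulometry_sizes(1)) {
  if (!is.list(curves)) curves <- list(curve = curves)
  if (is.null(names(curves))) names(curves) <- paste0("curve", seq_along(curves))
  d <- dplyr::bind_rows(lapply(names(curves), function(nm)
    tibble::tibble(curve = nm, size = sizes, F_B = as.numeric(curves[[nm]]))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$F_B,
                                  color = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "structuring element diameter (px)",
                  y = expression(F[B])) +
    ggplot2::theme_minimal()
}

#' Macro metrics of every classifier in a pipeline report
#'
#' @param object A `pipeline_report`.
#' @param ... Unused.
#' @return A ggplot comparing classifiers.
#' @export
autoplot.pipeline_report <- function(object, ...) {
  d <- tidyr::pivot_longer(glance(object),
                           c("macro_recall", "macro_f_measure"),
                           names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$classifier, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
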