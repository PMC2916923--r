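#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot: actual classes on the y axis, predicted on the x,
#'   tiles shaded by count and labelled with the count.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$actual <- factor(df$actual, levels = rev(rownames(object)))
  df$predicted <- factor(df$predicted, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted", y = "Actual", fill = "pairs") +
    ggplot2::theme_minimal()
}

#' Per-class metric bars
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot of precision, recall and MCC per class.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object)[c("class", "precision", "recall", "mcc")],
                            cols = c("precision", "recall", "mcc"),
                            names_to = "metric", values_to = "value")
  df$class <- factor(df$class, levels = object$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "Shared SCOP level", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked probability-bin counts per predicted level
#'
#' @param bins A tibble from [bin_probabilities()].
#' @return A ggplot: one bar per predicted level, stacked by probability
#'   bin.
#' @export
plot_probability_bins <- function(bins) {
  df <- tidyr::pivot_longer(bins, cols = c("p_lt_0.5", "p_eq_0.5",
                                           "p_mid", "p_ge_0.9"),
                            names_to = "bin", values_to = "n")
  df$bin <- factor(df$bin, levels = c("p_lt_0.5", "p_eq_0.5", "p_mid", "p_ge_0.9"),
                   labels = c("p < 0.5", "p = 0.5", "0.5 < p < 0.9", "p ≥ 0.9"))
  df$label <- factor(df$label, levels = bins$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n, fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Predicted shared level", y = "pairs",
                  fill = "prediction probability") +
    ggplot2::theme_minimal()
}
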