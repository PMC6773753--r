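#' @exportS3Method ggplot2::autoplot
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("actual", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 trans = "log1p", guide = "none") +
    ggplot2::labs(x = "Predicted", y = "Actual") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bd_pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = paste0("Precision-recall: ",
                                 attr(object, "positive"),
                                 " (AUC = ", round_display(auc_pr(object)),
                                 ")")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bd_evaluation <- function(object, ...) {
  m <- tidyr::pivot_longer(object$metrics,
                           cols = c("precision", "recall", "f1"),
                           names_to = "metric", values_to = "value")
  m$class <- factor(m$class, levels = object$metrics$class)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$class, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
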