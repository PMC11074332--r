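#' Plot a normalized confusion matrix
#'
#' Heatmap of row-normalized proportions (true grade on the y axis), the
#' conventional way per-grade correct-prediction rates are displayed.
#'
#' @param object a [confusion()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ddi_confusion
#' @export
autoplot.ddi_confusion <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$proportion)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(grade_levels())) +
    ggplot2::labs(x = "predicted grade", y = "true grade",
                  fill = "row\nproportion") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param object a [roc_auc_ovr()] result.
#' @param ... unused.
#' @return a ggplot of TPR (sensitivity) against FPR (1 - specificity), one
#'   curve per grade, AUC in the legend.
#' @method autoplot ddi_roc
#' @export
autoplot.ddi_roc <- function(object, ...) {
  cv <- object$curves
  lab <- sprintf("%s (AUC %.3f)", names(object$auc), object$auc)
  names(lab) <- names(object$auc)
  cv$grade_lab <- factor(lab[as.character(cv$grade)], levels = lab)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$grade_lab)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_colour_manual(
      values = setNames(c("#2ca02c", "#e6b800", "#ff8c00", "#d62728"),
                        lab[grade_levels()])) +
    ggplot2::labs(x = "false positive rate (1 - specificity)",
                  y = "true positive rate (sensitivity)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class evaluation metrics
#'
#' @param object a [metrics_report()] result.
#' @param ... unused.
#' @return a ggplot with one bar panel per metric.
#' @method autoplot ddi_metrics
#' @export
autoplot.ddi_metrics <- function(object, ...) {
  tb <- tidy(object) |>
    tidyr::pivot_longer(-c("grade", "n"), names_to = "metric")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$grade, y = .data$value,
                                   fill = .data$grade)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_manual(
      values = setNames(c("#2ca02c", "#e6b800", "#ff8c00", "#d62728"),
                        grade_levels())) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a member's training history
#'
#' @param object a trained `ddi_mlp`.
#' @param ... unused.
#' @return a ggplot of training and validation loss per epoch.
#' @method autoplot ddi_mlp
#' @export
autoplot.ddi_mlp <- function(object, ...) {
  if (is.null(object$history)) abort("member has no training history")
  tb <- tidyr::pivot_longer(object$history, -"epoch", names_to = "series")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}
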