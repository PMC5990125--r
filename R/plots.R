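# ggplot2 autoplot() methods. The bootstrap boxes follow the convention
# used throughout the package's reporting: colored boxes are quartiles,
# whiskers span the full range of the bootstrap AUC distribution.

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname bootstrap_auc
#' @param object A `bootstrap_summary`.
#' @export
autoplot.bootstrap_summary <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "AUC")) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", width = 0.4, fill = "#a6bddb") +
    ggplot2::geom_point(ggplot2::aes(y = .data$auc), shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "Bootstrap AUC",
                  title = sprintf("Bootstrap AUC (point %.3f, %d resamples)",
                                  object$point_auc, object$n_boot)) +
    ggplot2::theme_minimal()
}

#' @rdname auc_difference
#' @param object An `auc_difference`.
#' @export
autoplot.auc_difference <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 40, fill = "#a6bddb", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$ci, colour = "#2c7fb8") +
    ggplot2::labs(x = "Bootstrap AUC difference", y = "Replicates",
                  title = sprintf("dAUC = %+.3f, p = %.3g", object$delta,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname run_experiment
#' @param object A `hybrid_experiment`.
#' @param ... Unused.
#' @export
autoplot.hybrid_experiment <- function(object, ...) {
  boxes <- box_summary(object)
  ggplot2::ggplot(boxes, ggplot2::aes(x = .data$agent, fill = .data$agent)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity", width = 0.5) +
    ggplot2::facet_wrap(~horizon, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Bootstrap AUC") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
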