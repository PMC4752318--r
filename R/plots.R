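# ggplot2 views of fitted models and evaluation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training objective trace
#'
#' @param object a fitted `nrlmf`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nrlmf
#' @export
autoplot.nrlmf <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "AdaGrad sweep", y = "Objective",
                  title = "NRLMF training objective") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' Boxplots of AUC and AUPR across folds and repeats.
#'
#' @param object an `nrlmf_cv`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nrlmf_cv
#' @export
autoplot.nrlmf_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fold_metrics, c("auc", "aupr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Per-fold value",
                  title = sprintf("Cross-validation (%s)", toupper(object$setting))) +
    ggplot2::theme_minimal()
}

#' Plot a predicted-probability ranking
#'
#' Lollipop chart of the top-ranked candidate novel interactions.
#'
#' @param ranking tibble from [rank_novel_interactions()].
#' @param max_rows number of rows to display.
#' @return a ggplot.
#' @export
plot_ranking <- function(ranking, max_rows = 30) {
  df <- dplyr::slice_head(ranking, n = max_rows)
  df <- dplyr::mutate(df, pair = stats::reorder(
    paste(.data$drug_id, .data$target_id, sep = " - "), .data$probability))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$pair)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$pair),
                          color = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted interaction probability", y = NULL,
                  title = "Top candidate novel interactions") +
    ggplot2::theme_minimal()
}
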