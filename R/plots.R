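# ggplot2 displays for the main result types.

#' Plot class-conditional feature distributions
#'
#' Boxplots of each feature split by mutation class — the visual check that
#' deleterious mutations sit at conserved, buried, homogeneous sites with
#' large similarity-score changes.
#'
#' @param features Tibble with the five feature columns and a `label` column.
#' @return A ggplot.
#' @export
plot_feature_distributions <- function(features) {
  long <- features |>
    dplyr::select(dplyr::all_of(model_features()), "label") |>
    tidyr::pivot_longer(-"label", names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @exportS3Method
autoplot.cyp_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' @exportS3Method
autoplot.cyp_cv <- function(object, ...) {
  long <- object$folds |>
    tidyr::pivot_longer(c("q2", "recall", "precision", "mcc", "auc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Fold", y = NULL)
}

#' @exportS3Method
autoplot.feature_selection <- function(object, ...) {
  rep <- object$report
  rep$f_plot <- ifelse(is.finite(rep$f_score), rep$f_score, NA_real_)
  ggplot2::ggplot(rep, ggplot2::aes(x = stats::reorder(.data$feature,
                                                       .data$f_plot),
                                    y = .data$f_plot, fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$f_min, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "F-score", fill = "kept")
}
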