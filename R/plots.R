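# ggplot2 graphics for fitted pipelines and evaluation reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param roc a tibble from [roc_curve()] (or several row-bound together
#'   with a distinguishing `group` column).
#' @param colour optional name of a column mapping curves to colours.
#' @return A ggplot object.
#' @export
plot_roc <- function(roc, colour = NULL) {
  p <- ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate")
  if (!is.null(colour)) {
    p + ggplot2::geom_step(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p + ggplot2::geom_step()
  }
}

#' Heatmap of fused prediction scores
#'
#' @param object a `cmaf_fit` from [cmaf()].
#' @param ... unused.
#' @return A ggplot tile map of the fused score matrix, with known
#'   associations outlined.
#' @method autoplot cmaf_fit
#' @export
autoplot.cmaf_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease_id, y = .data$drug_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$cmaf)) +
    ggplot2::geom_point(data = df[df$known == 1L, ], size = 0.6) +
    ggplot2::scale_fill_viridis_c(name = "fused score", limits = c(0, 1)) +
    ggplot2::labs(x = "disease", y = "drug") +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank())
}

#' Fold-level AUC distribution per method
#'
#' @param object a `cmaf_cv` from [cross_validate()].
#' @param ... unused.
#' @return A ggplot boxplot of per-fold AUCs by method.
#' @method autoplot cmaf_cv
#' @export
autoplot.cmaf_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$method, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = NULL, y = "fold AUC")
}

#' Objective trace of a graph-regularized NMF fit
#'
#' @param object a `factor_pair` from [nmfria_fit()].
#' @param ... unused.
#' @return A ggplot line of the objective per multiplicative-update sweep.
#' @method autoplot factor_pair
#' @export
autoplot.factor_pair <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "update sweep", y = "regularized objective")
}
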