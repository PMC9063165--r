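#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUROC %.2f (%d%% CI %.2f-%.2f)",
                                  object$auroc, round(100 * object$level),
                                  object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot per-feature effects
#'
#' Horizontal bar chart of differences of logarithmised medians, negative
#' bars (higher in healthy controls) to the left, coloured by annotation.
#'
#' @param object An `effect_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.effect_tbl <- function(object, ...) {
  x <- as_tibble(object)
  x$feature_id <- factor(x$feature_id, levels = x$feature_id[order(x$effect)])
  ggplot2::ggplot(x, ggplot2::aes(x = .data$effect, y = .data$feature_id,
                                  fill = .data$annotation)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Difference of logarithmised medians (AD - HC)",
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a shrinkage trajectory
#'
#' Mean cross-validated AUROC (with one-sd ribbon) as features are
#' eliminated, with the chosen model size marked.
#'
#' @param model A `block_model`.
#' @return A ggplot.
#' @export
plot_cv_trajectory <- function(model) {
  tr <- model$cv_trajectory
  chosen <- tr$n_features[model$chosen_row]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$n_features,
                                   y = .data$cv_auroc_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cv_auroc_mean - .data$cv_auroc_sd,
                                      ymax = .data$cv_auroc_mean + .data$cv_auroc_sd),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Number of features", y = "Mean CV AUROC",
                  title = sprintf("Block %s: chosen size %d", model$block, chosen)) +
    ggplot2::theme_minimal()
}
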