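#' Publication-style evaluation plots
#'
#' Small ggplot2 helpers mirroring the figures a method-comparison study
#' reports: agreement scatter with the identity line, Bland-Altman plot,
#' per-group box plot and ROC curve.
#'
#' @param auto,manual paired numeric vectors of one variable.
#' @param label axis label for the variable.
#' @return A ggplot object.
#' @export
plot_agreement <- function(auto, manual, label = "noise (HU)") {
  df <- data.frame(manual = manual, auto = auto)
  ggplot2::ggplot(df, ggplot2::aes(x = manual, y = auto)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste("manual", label), y = paste("automatic", label)) +
    ggplot2::theme_classic()
}

#' @rdname plot_agreement
#' @param ba result of [bland_altman()].
#' @export
plot_bland_altman <- function(ba, label = "noise (HU)") {
  df <- data.frame(m = ba$means, d = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_low, ba$loa_high),
                        linetype = c(1, 2, 2), colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste("mean of methods,", label),
                  y = paste("automatic - manual,", label)) +
    ggplot2::theme_classic()
}

#' @rdname plot_agreement
#' @param records measurement data.frame with `quality_label`.
#' @param variable column to plot.
#' @export
plot_group_box <- function(records, variable = "snr") {
  records$quality_label <- factor(records$quality_label,
                                  levels = quality_levels)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$quality_label,
                               y = .data[[variable]])) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = variable) +
    ggplot2::theme_classic()
}

#' @rdname plot_agreement
#' @param roc a `roc_result` from [roc_analysis()].
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC %.2f (%.2f-%.2f)", roc$auc,
                                      roc$auc_ci[["low"]],
                                      roc$auc_ci[["high"]])) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_classic()
}

utils::globalVariables(c("fpr", "tpr", ".data"))
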