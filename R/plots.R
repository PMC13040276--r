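#' Confusion-matrix heatmap
#'
#' Row-normalized percentages (rounded half-up for display) of predicted
#' stage by true stage, darker tiles for higher proportions.
#'
#' @param object A `confusion_matrix` from [confusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = .data$reference,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$display_percent),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(stage_names())) +
    ggplot2::labs(x = "Predicted stage", y = "True stage",
                  fill = "Row\nproportion",
                  title = sprintf("Confusion matrix: %s", object$rater_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.confusion_matrix
#' @param x A `confusion_matrix`.
#' @param y Unused.
#' @export
plot.confusion_matrix <- function(x, y, ...) print(autoplot(x, ...))

#' Forest plot of stage-specific agreement
#'
#' Kappa point estimates with 95% intervals per stage, one series per
#' comparison group (e.g. embryologists vs models).
#'
#' @param stage_kappa The `stage_kappa` tibble of a report bundle.
#' @return A ggplot object.
#' @export
plot_stage_kappa <- function(stage_kappa) {
  df <- stage_kappa |>
    dplyr::mutate(stage_name = factor(decode_stage(.data$stage),
                                      levels = stage_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage_name, y = .data$estimate,
                                   color = .data$comparison,
                                   shape = .data$comparison)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::labs(x = NULL, y = "Weighted/Fleiss kappa", color = NULL,
                  shape = NULL, title = "Stage-specific agreement") +
    ggplot2::theme_minimal()
}

#' Stage-wise IoU medians with intervals
#'
#' @param iou_summary A tibble from [stagewise_iou_summary()].
#' @return A ggplot object.
#' @export
plot_iou_medians <- function(iou_summary) {
  df <- iou_summary |>
    dplyr::mutate(stage_name = factor(.data$stage_name,
                                      levels = stage_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage_name,
                                   y = .data$median_pct,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low_pct,
                                        ymax = .data$ci_high_pct),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Median IoU (%)", fill = NULL,
                  title = "Grad-CAM vs LIME spatial overlap by stage") +
    ggplot2::theme_minimal()
}
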