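# ggplot2 visualisations for the main result types.

#' ROC curve of an evaluation report
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  y <- object$labels
  ord <- order(object$scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y[ord] == 0) / sum(y == 0))
  df <- tibble::tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC %.3f, 95%% CI %.3f-%.3f)",
                      object$auc, object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::coord_equal()
}

#' Calibration plot
#' @param report An `evaluation_report`.
#' @return A ggplot of observed vs predicted rates by bin.
#' @export
plot_calibration <- function(report) {
  ggplot2::ggplot(report$calibration$bins,
                  ggplot2::aes(.data$mean_predicted, .data$observed_rate,
                               size = .data$n)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability", y = "Observed rate",
                  title = sprintf("Calibration (slope %.2f)",
                                  report$calibration$slope)) +
    ggplot2::guides(size = "none")
}

#' Decision-curve plot
#' @param report An `evaluation_report`.
#' @return A ggplot of net benefit against threshold probability.
#' @export
plot_decision_curve <- function(report) {
  long <- tidyr::pivot_longer(report$dca, -"threshold",
                              names_to = "strategy", values_to = "net_benefit")
  long$strategy <- sub("net_benefit_", "", long$strategy)
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$net_benefit,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.1, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit")
}

#' Calinski-Harabasz curve plot
#' @param scores Tibble with columns `k` and `score` (and optionally
#'   `patient_id`), as returned by [select_k()] or [cohort_k_selection()].
#' @return A ggplot of the CH score against k.
#' @export
plot_ch_curve <- function(scores) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data$k, .data$score))
  if ("patient_id" %in% names(scores)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                                alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p + ggplot2::scale_x_continuous(breaks = unique(scores$k)) +
    ggplot2::labs(x = "Number of clusters k", y = "Calinski-Harabasz index")
}

#' SHAP attribution summary plot
#' @param report An `evaluation_report` (uses its stored attributions).
#' @param max_features Show at most this many features.
#' @return A ggplot, features ordered by mean absolute attribution.
#' @export
plot_shap <- function(report, max_features = 15L) {
  att <- report$shap$attributions
  ord <- names(sort(vapply(att, function(x) mean(abs(x)), numeric(1)),
                    decreasing = TRUE))
  ord <- head(ord, max_features)
  long <- tidyr::pivot_longer(att[ord], dplyr::everything(),
                              names_to = "feature", values_to = "phi")
  long$feature <- factor(long$feature, levels = rev(ord))
  ggplot2::ggplot(long, ggplot2::aes(.data$phi, .data$feature)) +
    ggplot2::geom_jitter(height = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "SHAP attribution (logit scale)", y = NULL)
}

#' Habitat map slice plot
#' @param labeling A `habitat_labeling`.
#' @param slice Slice index along the third axis (default: middle of the
#'   lesion).
#' @return A ggplot raster of habitat labels for one axial slice.
#' @export
plot_habitats <- function(labeling, slice = NULL) {
  lab <- labeling$labels
  if (is.null(slice)) {
    zs <- which(apply(lab > 0, 3, any))
    slice <- zs[ceiling(length(zs) / 2)]
  }
  sl <- lab[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$habitat <- factor(ifelse(sl[as.matrix(df)] == 0, NA, sl[as.matrix(df)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$habitat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_d(na.value = "transparent", na.translate = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Habitats (slice %d)", slice))
}
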