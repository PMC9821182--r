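#' Plot a one-vs-rest ROC curve
#'
#' @param object a `roc_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = sprintf("One-vs-rest ROC (AUC = %.3f)",
                                  auc_trapezoid(object))) +
    ggplot2::theme_minimal()
}

#' Plot per-arm trial accuracies with mean and SD
#'
#' @param object an `experiment_result`.
#' @param ... unused.
#' @return a ggplot: one bar per arm (mean accuracy), +/- SD error bars,
#'   individual trials overplotted.
#' @export
autoplot.experiment_result <- function(object, ...) {
  per_trial <- tidy(object)
  summ <- dplyr::bind_rows(glance(object$baseline),
                           glance(object$assisted))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$arm,
                                     y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "grey80", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), width = 0.15) +
    ggplot2::geom_jitter(data = per_trial,
                         ggplot2::aes(y = .data$accuracy), width = 0.05) +
    ggplot2::labs(x = NULL, y = "Test accuracy",
                  title = "Baseline vs segmentation-assisted classification") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return a ggplot tile plot, rows = truth, columns = predicted.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' Display a fundus image, mask or probability map
#'
#' @param x a `fundus_image`, `nv_mask` or `probability_map`.
#' @param ... passed to [graphics::rasterImage()] machinery.
#' @export
plot.fundus_image <- function(x, ...) {
  plot_raster(x$pixels / 255, x$image_id)
}

#' @export
plot.nv_mask <- function(x, ...) plot_raster(x$pixels, x$image_id)

#' @export
plot.probability_map <- function(x, ...) plot_raster(x$pixels, x$image_id)

plot_raster <- function(px, title) {
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  plot(c(0, 1), c(0, 1), type = "n", axes = FALSE, xlab = "", ylab = "",
       main = title, asp = 1)
  graphics::rasterImage(grDevices::as.raster(px), 0, 0, 1, 1)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
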