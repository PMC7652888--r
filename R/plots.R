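# ggplot2 displays for scores, curves and experiment results.

#' Plot a ROC curve
#'
#' @param scores Numeric scores (larger = more abnormal), or a data frame
#'   with `score`/`lof` and `label` columns.
#' @param labels Binary labels when `scores` is a vector.
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels = NULL) {
  v <- scores_and_labels(scores, labels)
  pts <- roc_points(v$scores, v$labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = sprintf("ROC curve (AUC = %.3f)",
                                  roc_auc(v$scores, v$labels))) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @inheritParams plot_roc
#' @return A ggplot object.
#' @export
plot_pr <- function(scores, labels = NULL) {
  v <- scores_and_labels(scores, labels)
  pts <- pr_points(v$scores, v$labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(linewidth = 0.7, direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall (sensitivity)", y = "Precision",
                  title = sprintf("Precision-recall curve (AP = %.3f)",
                                  pr_auc(v$scores, v$labels))) +
    ggplot2::theme_minimal()
}

scores_and_labels <- function(scores, labels) {
  if (is.data.frame(scores)) {
    col <- if ("score" %in% names(scores)) "score" else "lof"
    list(scores = scores[[col]], labels = scores$label)
  } else {
    list(scores = scores, labels = labels)
  }
}

#' @export
autoplot.arm_result <- function(object, ...) {
  plot_roc(object$scores) +
    ggplot2::labs(title = sprintf("%s (seed %d): ROC-AUC = %.3f",
                                  object$arm, object$seed,
                                  object$report$roc_auc))
}

#' @export
autoplot.ablation_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$arm, y = .data$roc_auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4, colour = "grey40") +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = NULL, y = "Test ROC-AUC",
                  title = "Ablation arms across seeds") +
    ggplot2::theme_minimal()
}

#' Display a pseudo-color or grayscale image
#'
#' @param image A matrix, H x W x 3 array, `pseudo_color_image`, or
#'   `grayscale_pair_case` (plots the fused pseudo-color image).
#' @return A ggplot object (raster display, origin at the top-left).
#' @export
plot_image <- function(image) {
  if (inherits(image, "grayscale_pair_case")) image <- fuse_pseudo_color(image)
  if (inherits(image, "pseudo_color_image")) image <- image$pixels
  check_pixels(image)
  if (is.matrix(image)) {
    df <- expand.grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
    df$fill <- grDevices::gray(as.numeric(image))
  } else {
    df <- expand.grid(row = seq_len(dim(image)[1]), col = seq_len(dim(image)[2]))
    df$fill <- grDevices::rgb(as.numeric(image[, , 1]),
                              as.numeric(image[, , 2]),
                              as.numeric(image[, , 3]))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
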