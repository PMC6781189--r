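# ggplot2 visualisation helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Plot a class activation map as a heat map
#'
#' Uses the blue (low) to red (high) convention of endoscopic CAM overlays.
#'
#' @param object A `cam_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cam_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  df$value <- as.vector(object$values)[(df$col - 1) * nrow(object$values) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("#2166AC", "#F7F7F7", "#B2182B")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "activation") +
    ggplot2::theme_void()
}

#' Plot training loss curves
#'
#' @param object A `cam_fit`.
#' @param ... Unused.
#' @return A ggplot of the loss terms and validation loss per epoch.
#' @export
autoplot.cam_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("ce", "cam", "total", "val_loss"),
                           names_to = "term", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_epoch,
                        linetype = "dotted") +
    ggplot2::labs(y = "loss") +
    ggplot2::theme_minimal()
}

#' Overlay truth and activated-region contours on an image
#'
#' Truth lesion contour in green, activated-region contour in blue —
#' the standard convention for endoscopic localization figures.
#'
#' @param image A `labeled_image` or H x W x 3 array.
#' @param region Logical activated-region matrix (image resolution).
#' @param truth Optional logical truth mask; defaults to the image's own
#'   lesion mask.
#' @return A ggplot.
#' @export
plot_cam_overlay <- function(image, region, truth = NULL) {
  if (inherits(image, "labeled_image")) {
    if (is.null(truth)) truth <- image$lesion_mask
    image <- image$pixels
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  df <- tidyr::expand_grid(row = seq_len(H), col = seq_len(W))
  idx <- (df$col - 1) * H + df$row
  df$fill <- grDevices::rgb(as.vector(image[, , 1])[idx],
                            as.vector(image[, , 2])[idx],
                            as.vector(image[, , 3])[idx])
  contour_df <- function(mask, label) {
    d <- tidyr::expand_grid(row = seq_len(H), col = seq_len(W))
    d$z <- as.vector(mask + 0)[(d$col - 1) * H + d$row]
    d$which <- label
    d
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_contour(
      data = contour_df(truth, "truth"),
      ggplot2::aes(z = .data$z), breaks = 0.5, colour = "green3",
      linewidth = 0.7)
  }
  p + ggplot2::geom_contour(
    data = contour_df(region, "activated"),
    ggplot2::aes(z = .data$z), breaks = 0.5, colour = "blue",
    linewidth = 0.7)
}
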