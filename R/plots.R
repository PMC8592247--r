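#' Plot a zone-attention profile
#'
#' Bar chart of the per-zone attention fractions (Z11..Z33); the dashed line
#' marks the uniform level 1/9.
#'
#' @param object A `zone_profile` tibble from [zone_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$zone, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / 9, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(
      x = "zone", y = "attention fraction",
      title = "Zone-wise Grad-CAM attention",
      subtitle = sprintf("%d correctly classified image(s)", object$n_images[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot the training curves of a protocol run
#'
#' @param object A `chestnet_run`.
#' @param ... Unused.
#' @return A ggplot object (loss and accuracy per epoch, faceted by phase).
#' @export
autoplot.chestnet_run <- function(object, ...) {
  log <- tidy(object)
  if (nrow(log) == 0) abort("run has no logged epochs")
  long <- tidyr::pivot_longer(
    log, c("train_loss", "val_loss", "train_acc", "val_acc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase, .data$task), scales = "free") +
    ggplot2::labs(
      title = sprintf("Training curves: %s", object$variant),
      x = "epoch", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Render a phantom or an attention overlay with base graphics
#'
#' @param image Gray matrix in `[0, 255]` or an RGB array from
#'   [overlay_attention()].
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_image <- function(image, main = "") {
  op <- graphics::par(mar = c(0.5, 0.5, if (nzchar(main)) 2 else 0.5, 0.5))
  on.exit(graphics::par(op))
  if (length(dim(image)) == 2) {
    img <- t(image[nrow(image):1, ]) / 255
    graphics::image(img, col = grDevices::gray.colors(256, 0, 1), axes = FALSE, main = main)
  } else {
    rast <- grDevices::as.raster(image)
    graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE, xlab = "", ylab = "", main = main)
    graphics::rasterImage(rast, 0, 0, 1, 1)
  }
  invisible(NULL)
}
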