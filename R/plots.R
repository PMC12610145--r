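# ggplot2 views of the pipeline's result objects.

#' Plot training curves
#'
#' Loss and PSNR per epoch for training (and validation when recorded).
#'
#' @param object a `unet_history` tibble (from a trained model's `$history`).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot unet_history
#' @export
autoplot.unet_history <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"epoch", names_to = c("set", "measure"),
      names_sep = "_", values_to = "value"
    ) |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(
      x = "epoch", y = NULL, colour = NULL,
      title = "U-Net training: MSE loss and PSNR"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-slice segmentation metrics by filter arm
#'
#' @param object an `aaa_experiment`.
#' @param ... unused.
#' @return a ggplot (boxplots of MCC/DSC/JC/MSD per arm).
#' @method autoplot aaa_experiment
#' @export
autoplot.aaa_experiment <- function(object, ...) {
  d <- object$metrics |>
    tidyr::pivot_longer(c("mcc", "dsc", "jc", "msd"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(.data$arm, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Segmentation quality by denoising arm (held-out slices)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a severity confusion matrix
#'
#' @param object a [severity_confusion()] matrix.
#' @param ... unused.
#' @return a ggplot tile map (rows = predicted, columns = true).
#' @method autoplot confusion_matrix3
#' @export
autoplot.confusion_matrix3 <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$true, .data$predicted, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(severity_levels)) +
    ggplot2::labs(
      x = "true class", y = "predicted class",
      title = "Severity confusion matrix"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Display an image slice or mask
#'
#' @param object an [image2d()], [binary_mask()] or [probability_map()].
#' @param ... unused.
#' @return a ggplot raster with y flipped so row 1 is at the top.
#' @method autoplot image2d
#' @export
autoplot.image2d <- function(object, ...) {
  d <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    value = as.vector(unclass(object))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' @method autoplot binary_mask
#' @export
autoplot.binary_mask <- autoplot.image2d

#' @method autoplot probability_map
#' @export
autoplot.probability_map <- autoplot.image2d
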