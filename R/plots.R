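# ggplot2 methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Training and validation Dice loss plus validation DSC per epoch,
#' with the best epoch marked.
#'
#' @param object A `training_history` (the `history` element of an
#'   [train()] fit).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.training_history <- function(object, ...) {
  h <- object
  class(h) <- setdiff(class(h), "training_history")
  long <- rbind(
    tibble::tibble(epoch = h$epoch, value = h$train_loss,
                   series = "training Dice loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_loss,
                   series = "validation Dice loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_dsc,
                   series = "validation DSC"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  be <- attr(object, "best_epoch")
  if (!is.null(be) && be > 0)
    p <- p + ggplot2::geom_vline(xintercept = be, linetype = "dashed",
                                 colour = "grey50")
  p
}

#' Plot per-image test metrics
#'
#' Histogram of per-image DSC values from an evaluation report.
#'
#' @param object An [evaluate()] report.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_report <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object$per_image, ggplot2::aes(x = .data$dsc)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$summary$dsc,
                        linetype = "dashed") +
    ggplot2::labs(x = "per-image DSC", y = "images",
                  title = sprintf("%s: mean DSC %.3f", object$summary$model,
                                  object$summary$dsc)) +
    ggplot2::theme_minimal()
}

#' Display an image record with its mask outline
#'
#' Renders the RGB image as a raster with tumor pixels tinted red.
#'
#' @param record An `image_record` (raw or preprocessed).
#' @return A ggplot.
#' @export
plot_record <- function(record) {
  img <- record$image
  if (max(img) > 1) img <- img / 255
  fg <- record$mask != 0
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[fg] <- if (ch == 1) pmin(pl[fg] * 0.4 + 0.6, 1) else pl[fg] * 0.4
    img[, , ch] <- pl
  }
  d <- dim(img)
  df <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$fill <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = record$id, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
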