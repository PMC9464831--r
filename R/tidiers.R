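# broom-style accessors and ggplot2 graphics for fitted models.

#' Tidy the training history of a fitted model
#'
#' @param x a trained `gcld_model`.
#' @param ... unused.
#' @return tibble with one row per epoch: `epoch`, `loss`, `val_dice`, `lr`.
#' @export
tidy.gcld_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has not been trained", call. = FALSE)
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x a trained `gcld_model`.
#' @param ... unused.
#' @return tibble with variant, parameter count, epochs trained, final
#'   training loss, best and final validation Dice.
#' @export
glance.gcld_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    variant = x$cfg$variant,
    n_parameters = n_parameters(x$params),
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    best_val_dice = if (is.null(h)) NA_real_ else max(h$val_dice),
    final_val_dice = if (is.null(h)) NA_real_ else h$val_dice[nrow(h)])
}

#' Plot training curves
#'
#' Training loss and validation Dice per epoch, faceted.
#'
#' @param object a trained `gcld_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gcld_model <- function(object, ...) {
  h <- tidy(object)
  long <- rbind(
    data.frame(epoch = h$epoch, metric = "training loss", value = h$loss),
    data.frame(epoch = h$epoch, metric = "validation Dice", value = h$val_dice))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste("Training curves:", object$cfg$variant)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Overlay a prediction on an image
#'
#' Renders the RGB image with the reference mask outline region and the
#' predicted lesion region as translucent overlays.
#'
#' @param pair a sample pair (image + mask).
#' @param prob optional probability map `[H, W]` or `[H, W, 1, 1]`; when
#'   given, pixels above `threshold` are shaded.
#' @param threshold binarisation threshold for `prob`.
#' @return a ggplot object.
#' @export
plot_overlay <- function(pair, prob = NULL, threshold = 0.5) {
  img <- pair$image
  rgbs <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  h <- nrow(pair$mask); w <- ncol(pair$mask)
  df <- data.frame(x = rep(seq_len(w), each = h), y = rep(rev(seq_len(h)), w),
                   fill = rgbs, gt = as.vector(pair$mask == 1L))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_raster(data = df[df$gt, ], fill = "#00ff00", alpha = 0.25)
  if (!is.null(prob)) {
    pm <- drop(as_feature_map(prob)[, , 1L, 1L]) >= threshold
    dfp <- df[as.vector(pm), ]
    if (nrow(dfp)) gg <- gg + ggplot2::geom_raster(data = dfp, fill = "#ff0000", alpha = 0.25)
  }
  gg + ggplot2::coord_equal() + ggplot2::theme_void()
}
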