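#' Display a synthetic sample with its masks and zones
#'
#' Four-panel base-graphics view: the image, fine masks, coarse annotations
#' and occurrence zones.
#'
#' @param x A `synthetic_sample`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.synthetic_sample <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_img(to_grayscale(x$image), "image")
  show_img(x$fine_wrinkle_mask + 2 * x$fine_pore_mask, "fine masks (w=1, p=2)")
  show_img(x$coarse_wrinkle_annotation + 2 * x$coarse_pore_annotation,
           "coarse annotations")
  show_img(x$zones$wrinkle_zone + 2 * x$zones$pore_zone, "zones")
  invisible(x)
}

#' Display a two-channel prediction next to its ground truth
#'
#' @param pred \[H, W, 2\] prediction from [predict.skin_unet()].
#' @param ground_truth A `ground_truth_map`.
#' @return `NULL`, invisibly.
#' @export
plot_prediction <- function(pred, ground_truth) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_img(ground_truth$wrinkle, "wrinkle GT")
  show_img(pred[, , 1L], "wrinkle prediction")
  show_img(ground_truth$pore, "pore GT")
  show_img(pred[, , 2L], "pore prediction")
  invisible(NULL)
}

show_img <- function(m, main = "") {
  m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(m, axes = FALSE, col = grDevices::gray.colors(256),
                  main = main, useRaster = TRUE)
}
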