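#' Select binarization thresholds by grid search on a validation split
#'
#' For each class independently, picks the threshold that maximizes the
#' pooled IoU between binarized predictions and the binarized ground truth
#' on the given samples. This calibrates the operating point of the
#' continuous regression output; the default grid spans the useful part of
#' the 0-255 texture scale.
#'
#' @param model A trained `skin_unet`.
#' @param samples List of `synthetic_sample` objects (validation split).
#' @param ground_truth Matching list of `ground_truth_map` objects.
#' @param grid Numeric vector of candidate thresholds.
#' @return Named vector `c(wrinkle =, pore =)`.
#' @export
select_thresholds <- function(model, samples, ground_truth,
                              grid = c(2, 4, 8, 12, 16, 24, 32, 48, 64, 96, 128)) {
  preds <- lapply(samples, function(s) predict(model, s$image))
  best <- c(wrinkle = grid[1L], pore = grid[1L])
  for (cls in c("wrinkle", "pore")) {
    ch <- if (cls == "wrinkle") 1L else 2L
    best_iou <- -1
    for (th in grid) {
      inter <- 0; uni <- 0
      for (i in seq_along(samples)) {
        p <- preds[[i]][, , ch] > th
        g <- ground_truth[[i]][[cls]] > th
        inter <- inter + sum(p & g)
        uni <- uni + sum(p | g)
      }
      val <- if (uni == 0) 1 else inter / uni
      if (val > best_iou) {
        best_iou <- val
        best[[cls]] <- th
      }
    }
  }
  best
}
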