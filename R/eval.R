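#' Binarize a continuous prediction map
#'
#' @param map Numeric matrix.
#' @param threshold Scalar; pixels strictly above it are set.
#' @return Logical matrix.
#' @export
binarize <- function(map, threshold) {
  if (anyNA(map)) stop("map contains NA values")
  unclass(map) > threshold
}

#' Intersection over union of two binary masks
#'
#' `|X intersect Xhat| / |X union Xhat|`. When both masks are empty the IoU
#' is defined as 1 (perfect agreement on absence); when exactly one is empty
#' it is 0.
#'
#' @param truth,pred Logical (or 0/1) matrices of identical size.
#' @return Fraction in \[0, 1\].
#' @export
iou <- function(truth, pred) {
  if (!identical(dim(truth), dim(pred))) {
    stop("truth and pred must have identical dimensions")
  }
  a <- truth != 0
  b <- pred != 0
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' Aggregate IoU over an evaluation set
#'
#' Predicts both feature maps for every sample, binarizes predictions and
#' ground truth at the same per-class thresholds (the ground truth `X` of the
#' IoU definition is the continuous texture-valued GT, so it is binarized
#' with the prediction's threshold; alternatively the generator's fine truth
#' masks can be used). Aggregate values pool intersections and unions over
#' the whole set; per-image values are also returned.
#'
#' @param model A trained `skin_unet`.
#' @param samples List of `synthetic_sample` objects.
#' @param thresholds Named vector `c(wrinkle =, pore =)` on the 0-255
#'   prediction scale.
#' @param ground_truth List of `ground_truth_map` objects (required for
#'   `truth = "gt"`).
#' @param truth `"gt"`: compare against the binarized continuous GT;
#'   `"fine"`: compare against the generator's fine masks.
#' @return Object of class `iou_report`: list with `iou_wrinkle`, `iou_pore`
#'   (pooled), `per_image` (data frame) and `binarize_thresholds`.
#' @export
iou_report <- function(model, samples, thresholds = c(wrinkle = 64, pore = 32),
                       ground_truth = NULL, truth = c("gt", "fine")) {
  truth <- match.arg(truth)
  if (truth == "gt" && is.null(ground_truth)) {
    ground_truth <- lapply(samples, make_ground_truth)
  }
  inter <- c(wrinkle = 0, pore = 0)
  uni <- c(wrinkle = 0, pore = 0)
  per <- data.frame(image = seq_along(samples), iou_wrinkle = NA_real_,
                    iou_pore = NA_real_)
  for (i in seq_along(samples)) {
    pred <- predict(model, samples[[i]]$image)
    pw <- binarize(pred[, , 1L], thresholds[["wrinkle"]])
    pp <- binarize(pred[, , 2L], thresholds[["pore"]])
    if (truth == "gt") {
      tw <- binarize(ground_truth[[i]]$wrinkle, thresholds[["wrinkle"]])
      tp <- binarize(ground_truth[[i]]$pore, thresholds[["pore"]])
    } else {
      tw <- samples[[i]]$fine_wrinkle_mask
      tp <- samples[[i]]$fine_pore_mask
    }
    inter <- inter + c(sum(tw & pw), sum(tp & pp))
    uni <- uni + c(sum(tw | pw), sum(tp | pp))
    per$iou_wrinkle[i] <- iou(tw, pw)
    per$iou_pore[i] <- iou(tp, pp)
  }
  structure(list(
    iou_wrinkle = if (uni[["wrinkle"]] == 0) 1 else inter[["wrinkle"]] / uni[["wrinkle"]],
    iou_pore = if (uni[["pore"]] == 0) 1 else inter[["pore"]] / uni[["pore"]],
    per_image = per,
    binarize_thresholds = thresholds
  ), class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("<iou_report: wrinkle %.4f, pore %.4f over %d images>\n",
              x$iou_wrinkle, x$iou_pore, nrow(x$per_image)))
  invisible(x)
}

#' False-positive pixels outside an occurrence zone
#'
#' Counts predicted pixels that are neither true-feature pixels nor inside
#' the zone where the feature occurs; the measure of misplaced detections
#' that positional learning is meant to suppress.
#'
#' @param pred Logical prediction mask.
#' @param truth Logical truth mask.
#' @param zone Logical occurrence-zone mask.
#' @return Integer count.
#' @export
false_positives_outside_zone <- function(pred, truth, zone) {
  sum((pred != 0) & !(truth != 0) & !(zone != 0))
}

#' Ablation over a list of model configurations
#'
#' Trains every configuration with an identical seed, budget and dataset and
#' reports parameter count, final validation loss and pooled IoU per class,
#' plus false-positive counts outside the pore zone.
#'
#' @param configs Named list of [model_config()] objects.
#' @param train_samples,val_samples Lists of `synthetic_sample` objects.
#' @param config A [train_config()].
#' @param gt_args List of arguments forwarded to [make_ground_truth()].
#' @param thresholds Binarization thresholds for [iou_report()], or `NULL`
#'   (default) to calibrate them per trained row with [select_thresholds()]
#'   on the validation split.
#' @param init_seed Seed for weight initialization (shared by all rows).
#' @return Data frame with one row per configuration, of class
#'   `skin_ablation`.
#' @export
run_ablation <- function(configs, train_samples, val_samples,
                         config = train_config(), gt_args = list(),
                         thresholds = NULL, init_seed = 1L) {
  if (length(configs) < 1L) stop("need at least one configuration")
  if (is.null(names(configs))) names(configs) <- paste0("config", seq_along(configs))
  gt_train <- lapply(train_samples, function(s) do.call(make_ground_truth, c(list(s), gt_args)))
  gt_val <- lapply(val_samples, function(s) do.call(make_ground_truth, c(list(s), gt_args)))
  rows <- lapply(names(configs), function(nm) {
    cf <- configs[[nm]]
    model <- build_model(cf, seed = init_seed)
    fit <- train_model(model, train_samples, gt_train, config)
    th <- thresholds
    if (is.null(th)) th <- select_thresholds(fit$model, val_samples, gt_val)
    rep <- iou_report(fit$model, val_samples, th, ground_truth = gt_val)
    fp <- vapply(val_samples, function(s) {
      pred <- predict(fit$model, s$image)
      false_positives_outside_zone(binarize(pred[, , 2L], th[["pore"]]),
                                   s$fine_pore_mask, s$zones$pore_zone)
    }, numeric(1))
    data.frame(model = nm,
               n_params = count_parameters(fit$model),
               final_train_loss = tail(fit$history, 1),
               val_loss = validation_loss(fit$model, val_samples, gt_val),
               val_loss_interior = validation_loss(fit$model, val_samples,
                                                   gt_val, region = "interior"),
               iou_wrinkle = rep$iou_wrinkle,
               iou_pore = rep$iou_pore,
               fp_pore_outside_zone = mean(fp),
               th_wrinkle = th[["wrinkle"]],
               th_pore = th[["pore"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("skin_ablation", class(out))
  out
}

#' The four standard ablation configurations
#'
#' Vanilla network (depth 5, base 64), reduced (base 32), reduced with both
#' attention mechanisms, and the proposed model (reduced + attentions +
#' zero-padded input).
#'
#' @param pad_Z Input padding of the proposed configuration.
#' @param depth,base Architecture scale of the vanilla row; the reduced rows
#'   use `base / 2`.
#' @return Named list of [model_config()] objects.
#' @export
ablation_configs <- function(pad_Z = 32L, depth = 5L, base = 64L) {
  reduced <- max(1L, base %/% 2L)
  list(
    unet = model_config(depth = depth, base_channels = base),
    reduced = model_config(depth = depth, base_channels = reduced),
    reduced_attn = model_config(depth = depth, base_channels = reduced,
                                use_spatial_attention = TRUE,
                                use_additive_attention = TRUE),
    proposed = model_config(depth = depth, base_channels = reduced,
                            use_spatial_attention = TRUE,
                            use_additive_attention = TRUE, pad_Z = pad_Z)
  )
}
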