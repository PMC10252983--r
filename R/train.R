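#' Training configuration
#'
#' @param epochs Number of passes over the training set (>= 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Adam step size (>= 0).
#' @param optimizer Only `"adam"` is available.
#' @param seed Integer seed controlling initialization-independent training
#'   randomness (sample order).
#' @param crop_size Optional `(H, W)`: train on central crops of this size
#'   (must, after padding, be divisible by `2^(depth - 1)` of the model).
#'   `NULL` trains on full images.
#' @param loss Only `"mse"` is available: the network regresses the
#'   continuous texture-valued ground truth, so a magnitude-aware loss is
#'   required.
#' @return Object of class `skin_train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 4L, learning_rate = 1e-3,
                         optimizer = "adam", seed = 1L, loss = "mse",
                         crop_size = NULL) {
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "mse")
  if (epochs < 0L) stop("epochs must be >= 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (!is.null(crop_size)) {
    if (length(crop_size) != 2L || any(crop_size < 1)) {
      stop("crop_size must be a positive (H, W) pair")
    }
    crop_size <- as.integer(crop_size)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), loss = loss,
                 crop_size = crop_size),
            class = "skin_train_config")
}

central_crop <- function(m, hw) {
  d <- dim(m)
  if (d[1L] < hw[1L] || d[2L] < hw[2L]) {
    stop("crop_size exceeds the image size")
  }
  r0 <- (d[1L] - hw[1L]) %/% 2L
  c0 <- (d[2L] - hw[2L]) %/% 2L
  if (length(d) == 2L) {
    m[r0 + seq_len(hw[1L]), c0 + seq_len(hw[2L])]
  } else {
    m[r0 + seq_len(hw[1L]), c0 + seq_len(hw[2L]), , drop = FALSE]
  }
}

# recursive Adam update over the nested parameter/gradient lists
adam_step <- function(params, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(params)) {
    # match parameter and gradient subtrees by name (fall back to position
    # for unnamed lists, e.g. the per-level decoder list)
    if (!is.list(m) || length(m) < length(params)) m <- vector("list", length(params))
    if (!is.list(v) || length(v) < length(params)) v <- vector("list", length(params))
    keys <- names(params)
    for (i in seq_along(params)) {
      gi <- if (!is.null(keys) && keys[i] != "") grads[[keys[i]]] else grads[[i]]
      if (is.null(params[[i]]) || is.null(gi)) next
      res <- adam_step(params[[i]], gi, m[[i]], v[[i]], lr, t, beta1,
                       beta2, eps)
      params[[i]] <- res$p
      m[[i]] <- res$m
      v[[i]] <- res$v
    }
    return(list(p = params, m = m, v = v))
  }
  if (is.null(m)) m <- params * 0
  if (is.null(v)) v <- params * 0
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = params - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# assemble padded input tensor and padded two-channel target for one sample;
# targets are trained on the [0, 1] scale (ground truth / 255)
prepare_pair <- function(sample, gt, Z, crop_size = NULL) {
  img <- sample$image
  gw <- gt$wrinkle
  gp <- gt$pore
  if (!is.null(crop_size)) {
    img <- central_crop(img, crop_size)
    gw <- central_crop(gw, crop_size)
    gp <- central_crop(gp, crop_size)
  }
  x <- zero_pad_input(img, Z)
  hw <- dim(x)[1:2]
  t2 <- array(0, c(hw, 2L))
  t2[, , 1L] <- zero_pad_input(gw / 255, Z)
  t2[, , 2L] <- zero_pad_input(gp / 255, Z)
  list(x = x, target = t2)
}

#' Train a segmentation model with MSE loss
#'
#' Minimizes the mean squared error between the two-channel prediction and
#' the two-channel continuous ground truth (both on the zero-padded grid;
#' the ground truth is padded with zeros, so the network is also trained to
#' silence the padding frame). Training is deterministic for a given
#' configuration: fixed initialization (the model's build seed), a fixed
#' sample order drawn once from the training seed, and full-batch-order
#' reuse across epochs.
#'
#' @param model A `skin_unet`; updated in place and returned.
#' @param samples List of `synthetic_sample` objects (or any list with an
#'   `image` field).
#' @param ground_truth List of `ground_truth_map` objects of equal length,
#'   generated from the samples' coarse annotations.
#' @param config A [train_config()].
#' @param calibrate_bn After the last epoch, reset the batch-norm running
#'   statistics to the average batch statistics of the training set under
#'   the final weights (deterministic), so short schedules still yield
#'   well-normalized inference.
#' @param shuffle `"epoch"` (default): a fresh deterministic permutation of
#'   the training set every epoch; `"fixed"`: one permutation drawn from the
#'   seed and reused, which makes the loss history fully order-stable (e.g.
#'   exactly constant when the learning rate is zero).
#' @return List with `model` and `history` (per-epoch mean training loss, on
#'   the \[0, 1\]-scaled targets).
#' @export
train_model <- function(model, samples, ground_truth, config = train_config(),
                        calibrate_bn = TRUE, shuffle = c("epoch", "fixed")) {
  shuffle <- match.arg(shuffle)
  stopifnot(inherits(model, "skin_unet"), inherits(config, "skin_train_config"))
  if (length(samples) == 0L) stop("empty training set")
  if (length(samples) != length(ground_truth)) {
    stop("samples and ground_truth must have equal length")
  }
  Z <- model$config$pad_Z
  pairs <- Map(prepare_pair, samples, ground_truth,
               MoreArgs = list(Z = Z, crop_size = config$crop_size))
  if (config$epochs == 0L) {
    return(list(model = model, history = numeric(0)))
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(config$seed, 424243L))
  order_idx <- sample.int(length(pairs))
  batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
  m <- list(); v <- list(); t_step <- 0L
  history <- numeric(config$epochs)
  hw <- dim(pairs[[1L]]$x)[1:2]
  for (ep in seq_len(config$epochs)) {
    if (shuffle == "epoch") {
      set.seed(derive_seed(config$seed, 100000L + ep))
      order_idx <- sample.int(length(pairs))
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / config$batch_size))
    }
    ep_loss <- 0
    for (b in batches) {
      nb <- length(b)
      xb <- array(0, c(hw, model$config$in_channels, nb))
      tb <- array(0, c(hw, 2L, nb))
      for (j in seq_len(nb)) {
        xb[, , , j] <- pairs[[b[j]]]$x
        tb[, , , j] <- pairs[[b[j]]]$target
      }
      fwd <- unet_forward(model, xb, training = TRUE, keep_cache = TRUE)
      resid <- fwd$y - tb
      loss <- mean(resid^2)
      ep_loss <- ep_loss + loss * nb
      if (config$learning_rate > 0) {
        dy <- 2 * resid / length(resid)
        grads <- unet_backward(model, fwd$cache, dy)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, m, v, config$learning_rate,
                         t_step)
        model$params <- upd$p
        m <- upd$m
        v <- upd$v
      }
    }
    history[ep] <- ep_loss / length(pairs)
  }
  if (calibrate_bn) {
    # reset running statistics to the average batch statistics under the
    # final weights, so inference-mode normalization matches what training
    # converged to even after short schedules
    bcount <- 0L
    for (b in batches) {
      nb <- length(b)
      xb <- array(0, c(hw, model$config$in_channels, nb))
      for (j in seq_len(nb)) xb[, , , j] <- pairs[[b[j]]]$x
      bcount <- bcount + 1L
      unet_forward(model, xb, training = TRUE, momentum = 1 / bcount)
    }
  }
  list(model = model, history = history)
}

#' Mean squared error of a model on a labelled set
#'
#' Computed in inference mode. With `region = "objective"` (default) the
#' error is taken over the model's own output grid -- including the
#' zero-padding frame with its all-zero target -- i.e. exactly the quantity
#' the training minimizes and the one conventionally reported as validation
#' loss. With `region = "interior"` the padding frame is cropped first, so
#' models with different padding are compared on identical pixels. Targets
#' are on the \[0, 1\] scale (ground truth / 255).
#'
#' @param model A `skin_unet`.
#' @param samples,ground_truth As in [train_model()].
#' @param region `"objective"` or `"interior"`, see above.
#' @return Mean squared error (scalar).
#' @export
validation_loss <- function(model, samples, ground_truth,
                            region = c("objective", "interior")) {
  region <- match.arg(region)
  Z <- model$config$pad_Z
  losses <- vapply(seq_along(samples), function(i) {
    if (region == "objective") {
      pr <- prepare_pair(samples[[i]], ground_truth[[i]], Z)
      fwd <- unet_forward(model, pr$x, training = FALSE)
      mean((fwd$y - array(pr$target, dim(fwd$y)))^2)
    } else {
      pred <- predict(model, samples[[i]]$image) / 255
      tgt <- array(0, dim(pred))
      tgt[, , 1L] <- ground_truth[[i]]$wrinkle / 255
      tgt[, , 2L] <- ground_truth[[i]]$pore / 255
      mean((pred - tgt)^2)
    }
  }, numeric(1))
  mean(losses)
}

#' Predict wrinkle and pore maps for one image
#'
#' The image is zero-padded according to the model's configuration, passed
#' through the network in inference mode, and the padding frame is removed;
#' predictions are returned on the 0-255 texture scale.
#'
#' @param object A `skin_unet`.
#' @param image \[H, W, 3\] array in \[0, 1\].
#' @param ... Unused.
#' @return \[H, W, 2\] array: channel 1 the wrinkle map, channel 2 the pore
#'   map.
#' @export
predict.skin_unet <- function(object, image, ...) {
  x <- zero_pad_input(image, object$config$pad_Z)
  fwd <- unet_forward(object, x, training = FALSE)
  out <- fwd$y[, , , 1L]
  crop_padding(out, object$config$pad_Z) * 255
}
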