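#' Architecture descriptor of the segmentation network
#'
#' Fully determines the network and therefore its trainable-parameter count.
#' The channel plan follows the standard U-Net doubling scheme
#' `base, 2*base, 4*base, ...`; in the (default) bilinear upsampling variant
#' the bottleneck width is halved, which is the widely used configuration
#' whose depth-5 / base-64 instance has 17.3 M trainable parameters, and
#' whose half-width (base 32) "reduced" instance has 4.3 M.
#'
#' @param depth Number of resolution levels (>= 2).
#' @param base_channels Channels of the first level (>= 1); 64 for the
#'   vanilla network, 32 for the reduced one.
#' @param use_spatial_attention Apply a spatial attention block at the
#'   bottleneck (channel-wise max+mean pooling, 7x7 convolution, sigmoid).
#' @param use_additive_attention Gate every skip connection with an additive
#'   attention module.
#' @param pad_Z Total input zero-padding in pixels (even, >= 0); `Z/2` zeros
#'   are added on each side so the network sees the image border and can
#'   learn absolute position implicitly. Padding adds no parameters.
#' @param in_channels Input channels (RGB: 3).
#' @param out_channels Output channels (2: wrinkle and pore maps,
#'   concatenated).
#' @param upsample_mode `"bilinear_then_conv"` (default) or
#'   `"transposed_conv"`.
#' @param channel_doubling Logical scalar or vector of length `depth - 1`:
#'   whether the channel width doubles at each descent.
#' @return Object of class `skin_model_config`.
#' @export
model_config <- function(depth = 5L, base_channels = 64L,
                         use_spatial_attention = FALSE,
                         use_additive_attention = FALSE,
                         pad_Z = 0L, in_channels = 3L, out_channels = 2L,
                         upsample_mode = c("bilinear_then_conv",
                                           "transposed_conv"),
                         channel_doubling = TRUE) {
  upsample_mode <- match.arg(upsample_mode)
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  pad_Z <- as.integer(pad_Z)
  if (pad_Z < 0L || pad_Z %% 2L != 0L) stop("pad_Z must be even and >= 0")
  doubling <- rep_len(as.logical(channel_doubling), depth - 1L)
  ch <- integer(depth)
  ch[1L] <- as.integer(base_channels)
  for (i in 2:depth) ch[i] <- ch[i - 1L] * (1L + doubling[i - 1L])
  if (upsample_mode == "bilinear_then_conv") {
    ch[depth] <- max(1L, ch[depth] %/% 2L)
  }
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 channels = ch, channel_doubling = doubling,
                 use_spatial_attention = isTRUE(use_spatial_attention),
                 use_additive_attention = isTRUE(use_additive_attention),
                 pad_Z = pad_Z, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 upsample_mode = upsample_mode),
            class = "skin_model_config")
}

# decoder channel bookkeeping; level l = 1 is the deepest decoder stage
decoder_plan <- function(config) {
  depth <- config$depth
  ch <- config$channels
  plan <- vector("list", depth - 1L)
  d_in <- ch[depth]
  for (l in seq_len(depth - 1L)) {
    skip_ch <- ch[depth - l]
    if (config$upsample_mode == "transposed_conv") {
      d_up <- max(1L, d_in %/% 2L)
    } else {
      d_up <- d_in
    }
    cat_in <- skip_ch + d_up
    out <- if (depth - l - 1L >= 1L) ch[depth - l - 1L] else ch[1L]
    if (config$upsample_mode == "transposed_conv") out <- skip_ch
    mid <- max(1L, cat_in %/% 2L)
    plan[[l]] <- list(skip_ch = skip_ch, d_in = d_in, d_up = d_up,
                      cat_in = cat_in, mid = mid, out = out,
                      inter = max(1L, skip_ch %/% 2L))
    d_in <- out
  }
  plan
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_dc <- function(cin, mid, cout) {
  list(w1 = he_init(3L, cin, mid), g1 = rep(1, mid), b1 = rep(0, mid),
       w2 = he_init(3L, mid, cout), g2 = rep(1, cout), b2 = rep(0, cout))
}

new_dc_state <- function(mid, cout) {
  list(rm1 = rep(0, mid), rv1 = rep(1, mid),
       rm2 = rep(0, cout), rv2 = rep(1, cout))
}

#' Build a segmentation model from a configuration
#'
#' Instantiates all trainable weights (He-normal initialization, deterministic
#' for a given seed) and the batch-norm running statistics. The amount of
#' input zero-padding influences neither the weights nor their
#' initialization, so models built with different `pad_Z` but the same seed
#' have identical parameters.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `skin_unet` (an environment with fields `config`,
#'   `params`, `state`).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "skin_model_config"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  depth <- config$depth
  ch <- config$channels
  params <- list(enc = vector("list", depth), dec = vector("list", depth - 1L))
  state <- list(enc = vector("list", depth), dec = vector("list", depth - 1L))
  params$enc[[1L]] <- new_dc(config$in_channels, ch[1L], ch[1L])
  state$enc[[1L]] <- new_dc_state(ch[1L], ch[1L])
  for (i in 2:depth) {
    params$enc[[i]] <- new_dc(ch[i - 1L], ch[i], ch[i])
    state$enc[[i]] <- new_dc_state(ch[i], ch[i])
  }
  if (config$use_spatial_attention) {
    params$sa <- list(w = he_init(7L, 2L, 1L), b = 0)
  }
  plan <- decoder_plan(config)
  for (l in seq_len(depth - 1L)) {
    pl <- plan[[l]]
    lev <- list()
    if (config$upsample_mode == "transposed_conv") {
      lev$up_w <- array(rnorm(4L * pl$d_in * pl$d_up,
                              sd = sqrt(2 / (4 * pl$d_in))),
                        c(2L, 2L, pl$d_in, pl$d_up))
    }
    if (config$use_additive_attention) {
      lev$aam <- list(
        wd = he_init(3L, pl$d_up, pl$d_up), gd = rep(1, pl$d_up),
        bd = rep(0, pl$d_up),
        w1 = he_init(1L, pl$skip_ch, pl$inter),
        w2 = he_init(1L, pl$d_up, pl$inter),
        b = rep(0, pl$inter),
        psi_w = he_init(1L, pl$inter, 1L), psi_b = 0)
      state$dec[[l]]$aam <- list(rm = rep(0, pl$d_up), rv = rep(1, pl$d_up))
    }
    lev$dc <- new_dc(pl$cat_in, pl$mid, pl$out)
    state$dec[[l]]$dc <- new_dc_state(pl$mid, pl$out)
    params$dec[[l]] <- lev
  }
  last_out <- plan[[depth - 1L]]$out
  params$out <- list(w = he_init(1L, last_out, config$out_channels),
                     b = rep(0, config$out_channels))
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- params
  model$state <- state
  model$plan <- plan
  class(model) <- "skin_unet"
  model
}

#' Count trainable parameters of a model
#'
#' Counts every trainable scalar: convolution weights and biases and the
#' batch-norm scale/shift pairs. Running statistics are not trainable and are
#' excluded.
#'
#' @param model A `skin_unet` from [build_model()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "skin_unet"))
  as.integer(sum(rapply(model$params, length, how = "unlist")))
}

#' Zero-pad an image for positional learning
#'
#' Adds a border of `Z/2` zeros on each side, producing an
#' `(H+Z) x (W+Z)` image whose interior equals the input. The constant zero
#' frame is the positional reference the convolutional network exploits.
#'
#' @param image Matrix or \[H, W, C\] array.
#' @param Z Total padding in pixels (even, >= 0).
#' @return Padded matrix/array.
#' @export
zero_pad_input <- function(image, Z) {
  Z <- as.integer(Z)
  if (Z < 0L || Z %% 2L != 0L) stop("Z must be even and >= 0")
  if (Z == 0L) return(image)
  h <- Z %/% 2L
  d <- dim(image)
  if (length(d) == 2L) {
    out <- matrix(0, d[1L] + Z, d[2L] + Z)
    out[h + seq_len(d[1L]), h + seq_len(d[2L])] <- image
  } else {
    out <- array(0, c(d[1L] + Z, d[2L] + Z, d[3L]))
    out[h + seq_len(d[1L]), h + seq_len(d[2L]), ] <- image
  }
  out
}

crop_padding <- function(x, Z) {
  if (Z == 0L) return(x)
  h <- Z %/% 2L
  d <- dim(x)
  if (length(d) == 2L) {
    x[(h + 1L):(d[1L] - h), (h + 1L):(d[2L] - h)]
  } else {
    x[(h + 1L):(d[1L] - h), (h + 1L):(d[2L] - h), , drop = FALSE]
  }
}

# ---- double conv block ----

dc_forward <- function(p, st, x, training, momentum = 0.1) {
  c1 <- conv_fwd(x, p$w1)
  bn1 <- bn_fwd(c1, p$g1, p$b1, st$rm1, st$rv1, training, momentum)
  r1 <- relu_fwd(bn1$y)
  c2 <- conv_fwd(r1$y, p$w2)
  bn2 <- bn_fwd(c2, p$g2, p$b2, st$rm2, st$rv2, training, momentum)
  r2 <- relu_fwd(bn2$y)
  list(y = r2$y,
       cache = list(x = x, bn1 = bn1[c("xhat", "ivar", "dims")],
                    m1 = r1$mask, h1 = r1$y,
                    bn2 = bn2[c("xhat", "ivar", "dims")], m2 = r2$mask),
       state = list(rm1 = bn1$rm, rv1 = bn1$rv, rm2 = bn2$rm, rv2 = bn2$rv))
}

dc_backward <- function(p, cache, dy, need_dx = TRUE) {
  d2 <- bn_bwd(cache$bn2, p$g2, dy * cache$m2)
  cv2 <- conv_bwd(cache$h1, p$w2, d2$dx, need_dx = TRUE)
  d1 <- bn_bwd(cache$bn1, p$g1, cv2$dx * cache$m1)
  cv1 <- conv_bwd(cache$x, p$w1, d1$dx, need_dx = need_dx)
  list(dx = if (need_dx) cv1$dx else NULL,
       grads = list(w1 = cv1$dw, g1 = d1$dgamma, b1 = d1$dbeta,
                    w2 = cv2$dw, g2 = d2$dgamma, b2 = d2$dbeta))
}

# ---- spatial attention (bottleneck) ----

sa_forward <- function(p, x) {
  d <- dim(x)
  C <- d[3L]; N <- d[4L]
  m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * N, C)
  amax <- max.col(m, ties.method = "first")
  vmax <- m[cbind(seq_len(nrow(m)), amax)]
  vmean <- rowMeans(m)
  pooled <- array(0, c(d[1L], d[2L], 2L, N))
  pooled[, , 1L, ] <- array(vmax, c(d[1L], d[2L], N))
  pooled[, , 2L, ] <- array(vmean, c(d[1L], d[2L], N))
  s <- conv_fwd(pooled, p$w, p$b)
  g <- sigmoid(s)
  list(y = gate_mul(x, g),
       cache = list(x = x, pooled = pooled, g = g, amax = amax))
}

sa_backward <- function(p, cache, dy) {
  x <- cache$x
  d <- dim(x)
  C <- d[3L]; N <- d[4L]
  dg <- reduce_channels(dy * x)
  dx <- gate_mul(dy, cache$g)
  ds <- dg * cache$g * (1 - cache$g)
  cv <- conv_bwd(cache$pooled, p$w, ds, need_dx = TRUE, has_bias = TRUE)
  dpool <- cv$dx
  # route max-channel gradient to the argmax channel, spread mean gradient
  dmax <- as.numeric(dpool[, , 1L, ])
  dmean <- as.numeric(dpool[, , 2L, ]) / C
  dxp <- matrix(dmean, d[1L] * d[2L] * N, C)
  idx <- cbind(seq_along(cache$amax), cache$amax)
  dxp[idx] <- dxp[idx] + dmax
  dxp <- aperm(array(dxp, c(d[1L], d[2L], N, C)), c(1L, 2L, 4L, 3L))
  list(dx = dx + dxp, grads = list(w = cv$dw, b = cv$db))
}

# ---- additive attention gate ----

aam_forward <- function(p, st, skip, d_up, training, momentum = 0.1) {
  cd <- conv_fwd(d_up, p$wd)
  bnd <- bn_fwd(cd, p$gd, p$bd, st$rm, st$rv, training, momentum)
  rd <- relu_fwd(bnd$y)
  proc <- rd$y
  a1 <- conv_fwd(skip, p$w1)
  a2 <- conv_fwd(proc, p$w2)
  pre_in <- add_channel_bias(a1 + a2, p$b)
  rp <- relu_fwd(pre_in)
  s <- conv_fwd(rp$y, p$psi_w, p$psi_b)
  g <- sigmoid(s)
  gated <- gate_mul(skip, g)
  list(y = cat_channels(gated, proc), gate = g,
       cache = list(skip = skip, d_up = d_up,
                    bnd = bnd[c("xhat", "ivar", "dims")], md = rd$mask,
                    proc = proc, mp = rp$mask, pre = rp$y, g = g),
       state = list(rm = bnd$rm, rv = bnd$rv))
}

aam_backward <- function(p, cache, dy) {
  skip_ch <- dim(cache$skip)[3L]
  dgated <- dy[, , seq_len(skip_ch), , drop = FALSE]
  dproc_direct <- dy[, , (skip_ch + 1L):dim(dy)[3L], , drop = FALSE]
  g <- cache$g
  dskip <- gate_mul(dgated, g)
  dg <- reduce_channels(dgated * cache$skip)
  ds <- dg * g * (1 - g)
  cpsi <- conv_bwd(cache$pre, p$psi_w, ds, need_dx = TRUE, has_bias = TRUE)
  dpre_in <- cpsi$dx * cache$mp
  db <- channel_sums(dpre_in)
  c1 <- conv_bwd(cache$skip, p$w1, dpre_in, need_dx = TRUE)
  c2 <- conv_bwd(cache$proc, p$w2, dpre_in, need_dx = TRUE)
  dskip <- dskip + c1$dx
  dproc <- dproc_direct + c2$dx
  dbn <- bn_bwd(cache$bnd, p$gd, dproc * cache$md)
  cd <- conv_bwd(cache$d_up, p$wd, dbn$dx, need_dx = TRUE)
  list(dskip = dskip, dd_up = cd$dx,
       grads = list(wd = cd$dw, gd = dbn$dgamma, bd = dbn$dbeta,
                    w1 = c1$dw, w2 = c2$dw, b = db,
                    psi_w = cpsi$dw, psi_b = cpsi$db))
}

# ---- full network ----

unet_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                         momentum = 0.1) {
  config <- model$config
  depth <- config$depth
  x <- as_batch(x)
  d <- dim(x)
  div <- 2L^(depth - 1L)
  if (d[1L] %% div != 0L || d[2L] %% div != 0L) {
    stop("input spatial size ", d[1L], "x", d[2L],
         " (after padding) is not divisible by 2^(depth-1) = ", div)
  }
  if (d[3L] != config$in_channels) {
    stop("expected ", config$in_channels, " input channels, got ", d[3L])
  }
  cache <- list(enc = vector("list", depth), pool = vector("list", depth - 1L),
                dec = vector("list", depth - 1L))
  enc_out <- vector("list", depth)
  cur <- x
  for (i in seq_len(depth)) {
    if (i > 1L) {
      mp <- maxpool_fwd(cur)
      cache$pool[[i - 1L]] <- list(idx = mp$idx, xdim = dim(cur))
      cur <- mp$y
    }
    blk <- dc_forward(model$params$enc[[i]], model$state$enc[[i]], cur, training,
                      momentum)
    if (training) model$state$enc[[i]][names(blk$state)] <- blk$state
    cache$enc[[i]] <- blk$cache
    enc_out[[i]] <- blk$y
    cur <- blk$y
  }
  if (config$use_spatial_attention) {
    sa <- sa_forward(model$params$sa, cur)
    cache$sa <- sa$cache
    cur <- sa$y
  }
  for (l in seq_len(depth - 1L)) {
    skip <- enc_out[[depth - l]]
    lev <- model$params$dec[[l]]
    lc <- list(d_in_dim = dim(cur))
    if (config$upsample_mode == "transposed_conv") {
      lc$up_in <- cur
      d_up <- cpp_convT2_fwd(cur, dim(cur), lev$up_w, dim(lev$up_w))
    } else {
      d_up <- upsample_fwd(cur, dim(skip)[1:2])
    }
    if (config$use_additive_attention) {
      am <- aam_forward(lev$aam, model$state$dec[[l]]$aam, skip, d_up, training,
                        momentum)
      if (training) model$state$dec[[l]]$aam[names(am$state)] <- am$state
      lc$aam <- am$cache
      z <- am$y
    } else {
      z <- cat_channels(skip, d_up)
    }
    lc$skip_ch <- dim(skip)[3L]
    blk <- dc_forward(lev$dc, model$state$dec[[l]]$dc, z, training, momentum)
    if (training) model$state$dec[[l]]$dc[names(blk$state)] <- blk$state
    lc$dc <- blk$cache
    cache$dec[[l]] <- lc
    cur <- blk$y
  }
  cache$head_in <- cur
  y <- conv_fwd(cur, model$params$out$w, model$params$out$b)
  list(y = y, cache = if (keep_cache) cache else NULL)
}

unet_backward <- function(model, cache, dy) {
  config <- model$config
  depth <- config$depth
  grads <- list(enc = vector("list", depth), dec = vector("list", depth - 1L))
  co <- conv_bwd(cache$head_in, model$params$out$w, dy, need_dx = TRUE,
                 has_bias = TRUE)
  grads$out <- list(w = co$dw, b = co$db)
  cur <- co$dx
  denc <- vector("list", depth) # gradient accumulators for encoder outputs
  for (l in rev(seq_len(depth - 1L))) {
    lc <- cache$dec[[l]]
    lev <- model$params$dec[[l]]
    blk <- dc_backward(lev$dc, lc$dc, cur, need_dx = TRUE)
    grads$dec[[l]]$dc <- blk$grads
    dz <- blk$dx
    if (config$use_additive_attention) {
      am <- aam_backward(lev$aam, lc$aam, dz)
      grads$dec[[l]]$aam <- am$grads
      dskip <- am$dskip
      dd_up <- am$dd_up
    } else {
      dskip <- dz[, , seq_len(lc$skip_ch), , drop = FALSE]
      dd_up <- dz[, , (lc$skip_ch + 1L):dim(dz)[3L], , drop = FALSE]
    }
    denc[[depth - l]] <- dskip
    if (config$upsample_mode == "transposed_conv") {
      ct <- cpp_convT2_bwd(lc$up_in, dim(lc$up_in), lev$up_w, dim(lev$up_w),
                           dd_up)
      grads$dec[[l]]$up_w <- ct$dw
      cur <- ct$dx
    } else {
      cur <- upsample_bwd(dd_up, lc$d_in_dim[1:2])
    }
  }
  if (config$use_spatial_attention) {
    sa <- sa_backward(model$params$sa, cache$sa, cur)
    grads$sa <- sa$grads
    cur <- sa$dx
  }
  for (i in rev(seq_len(depth))) {
    if (i < depth && !is.null(denc[[i]])) cur <- cur + denc[[i]]
    blk <- dc_backward(model$params$enc[[i]], cache$enc[[i]], cur,
                       need_dx = i > 1L)
    grads$enc[[i]] <- blk$grads
    if (i > 1L) {
      pc <- cache$pool[[i - 1L]]
      cur <- maxpool_bwd(pc$idx, blk$dx, pc$xdim)
    }
  }
  grads
}

#' Standalone spatial-attention operation
#'
#' Channel-wise max and mean maps are concatenated (2 channels), convolved
#' (same-size 7x7 by default) and squashed with a sigmoid; the resulting
#' per-pixel attention in (0, 1) is broadcast-multiplied onto the input.
#'
#' @param features \[H, W, C\] or \[H, W, C, N\] feature volume.
#' @param w Convolution weights \[k, k, 2, 1\] (odd `k`).
#' @param b Convolution bias (scalar).
#' @return List with `output` (same shape as `features`) and `attention`
#'   (single-channel map in (0, 1)).
#' @export
spatial_attention <- function(features, w, b = 0) {
  x <- as_batch(features)
  res <- sa_forward(list(w = w, b = b), x)
  out <- res$y
  att <- res$cache$g
  if (length(dim(features)) == 3L) {
    out <- array(out, dim(features))
    att <- matrix(att[, , 1L, 1L], dim(features)[1L], dim(features)[2L])
  }
  list(output = out, attention = att)
}

#' Standalone additive attention gate
#'
#' The decoder features (query) are upsampled to the encoder resolution and
#' passed through convolution, batch normalization (inference statistics) and
#' ReLU; the gate `sigmoid(psi(relu(W1 k + W2 q + b)))` is reduced to a
#' single channel and multiplied onto the encoder features (key/value),
#' which are finally concatenated with the processed decoder features.
#'
#' @param encoder_feats \[H, W, Ce\] encoder feature volume.
#' @param decoder_feats \[h, w, Cd\] decoder feature volume at half the
#'   spatial size (it is upsampled to `H x W`).
#' @param weights List with elements `wd` \[3, 3, Cd, Cd\], `gd`, `bd`
#'   (batch-norm scale/shift, length Cd), `w1` \[1, 1, Ce, Ci\], `w2`
#'   \[1, 1, Cd, Ci\], `b` (length Ci), `psi_w` \[1, 1, Ci, 1\], `psi_b`
#'   (scalar).
#' @return List with `output` (\[H, W, Ce + Cd\]) and `gate` (\[H, W\] map in
#'   (0, 1)).
#' @export
additive_attention_gate <- function(encoder_feats, decoder_feats, weights) {
  enc <- as_batch(encoder_feats)
  dec <- as_batch(decoder_feats)
  if (any(dim(enc)[1:2] != 2L * dim(dec)[1:2])) {
    stop("decoder features must be at half the encoder spatial size")
  }
  d_up <- upsample_fwd(dec, dim(enc)[1:2])
  cd <- dim(dec)[3L]
  st <- list(rm = rep(0, cd), rv = rep(1, cd))
  res <- aam_forward(weights, st, enc, d_up, training = FALSE)
  out <- res$y
  if (length(dim(encoder_feats)) == 3L) {
    out <- array(out, c(dim(enc)[1:2], dim(out)[3L]))
  }
  list(output = out,
       gate = matrix(res$gate[, , 1L, 1L], dim(enc)[1L], dim(enc)[2L]))
}

#' Construct the weight list of an additive attention gate
#'
#' @param encoder_channels,decoder_channels Channel counts of the two inputs.
#' @param inter_channels Internal projection width; defaults to half the
#'   encoder channels.
#' @param seed Seed for the random initialization.
#' @return Weight list as consumed by [additive_attention_gate()].
#' @export
aam_weights <- function(encoder_channels, decoder_channels,
                        inter_channels = max(1L, encoder_channels %/% 2L),
                        seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  list(wd = he_init(3L, decoder_channels, decoder_channels),
       gd = rep(1, decoder_channels), bd = rep(0, decoder_channels),
       w1 = he_init(1L, encoder_channels, inter_channels),
       w2 = he_init(1L, decoder_channels, inter_channels),
       b = rep(0, inter_channels),
       psi_w = he_init(1L, inter_channels, 1L), psi_b = 0)
}

#' @export
print.skin_model_config <- function(x, ...) {
  cat("<skin_model_config>\n")
  cat("  depth:", x$depth, " channels:", paste(x$channels, collapse = "-"), "\n")
  cat("  spatial attention:", x$use_spatial_attention,
      " additive attention:", x$use_additive_attention, "\n")
  cat("  pad_Z:", x$pad_Z, " upsampling:", x$upsample_mode, "\n")
  invisible(x)
}

#' @export
print.skin_unet <- function(x, ...) {
  np <- count_parameters(x)
  cat(sprintf("<skin_unet: depth %d, base %d, %s%s%s%.1f M parameters (%d)>\n",
              x$config$depth, x$config$base_channels,
              if (x$config$use_spatial_attention) "spatial attention, " else "",
              if (x$config$use_additive_attention) "additive attention, " else "",
              if (x$config$pad_Z > 0) sprintf("Z=%d, ", x$config$pad_Z) else "",
              np / 1e6, np))
  invisible(x)
}

#' Layer-by-layer summary of a model
#'
#' @param object A `skin_unet`.
#' @param ... Unused.
#' @return A data frame with one row per weight tensor (name, shape,
#'   parameter count), invisibly; printed as a table.
#' @export
summary.skin_unet <- function(object, ...) {
  tensors <- flatten_tensors(object$params)
  df <- data.frame(
    tensor = names(tensors),
    shape = vapply(tensors, function(t) paste(if (is.null(dim(t))) length(t) else dim(t),
                                              collapse = "x"), character(1)),
    params = vapply(tensors, length, numeric(1)),
    row.names = NULL)
  cat(sprintf("skin_unet with %d trainable parameters (%.1f M)\n",
              count_parameters(object), count_parameters(object) / 1e6))
  print(df, row.names = FALSE)
  invisible(df)
}

# flatten a nested parameter list into a flat named list of tensors
flatten_tensors <- function(p, prefix = "") {
  out <- list()
  keys <- names(p)
  if (is.null(keys)) keys <- as.character(seq_along(p))
  for (i in seq_along(p)) {
    v <- p[[i]]
    nm <- if (is.null(names(p)) || names(p)[i] == "") as.character(i) else names(p)[i]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) {
      out <- c(out, flatten_tensors(v, key))
    } else if (!is.null(v)) {
      out[[key]] <- v
    }
  }
  out
}
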