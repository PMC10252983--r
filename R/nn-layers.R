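# Layer primitives for the segmentation network. Feature volumes are numeric
# arrays [H, W, C, N]; convolution weights are [k, k, Cin, Cout]. Each *_fwd
# returns the output plus whatever the matching *_bwd needs.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array feature volume")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

conv_fwd <- function(x, w, b = NULL) {
  cpp_conv2d_fwd(x, dim(x), w, dim(w), if (is.null(b)) numeric(0) else b)
}

conv_bwd <- function(x, w, dy, need_dx = TRUE, has_bias = FALSE) {
  cpp_conv2d_bwd(x, dim(x), w, dim(w), dy, need_dx, has_bias)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# per-channel statistics over (H, W, N)
channel_stat <- function(m, n_channels, n_batch, fun = rowMeans) {
  fun(matrix(.colMeans(m, nrow(m), ncol(m)), n_channels, n_batch))
}

bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  C <- d[3L]; N <- d[4L]
  m <- matrix(x, d[1L] * d[2L], C * N)
  if (training) {
    mu <- rowMeans(matrix(.colMeans(m, nrow(m), ncol(m)), C, N))
    ex2 <- rowMeans(matrix(.colMeans(m * m, nrow(m), ncol(m)), C, N))
    var <- pmax(ex2 - mu^2, 0)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * var
  } else {
    mu <- rm
    var <- rv
  }
  ivar <- 1 / sqrt(var + eps)
  xhat <- sweep(sweep(m, 2L, rep(mu, times = N), "-"), 2L,
                rep(ivar, times = N), "*")
  y <- sweep(sweep(xhat, 2L, rep(gamma, times = N), "*"), 2L,
             rep(beta, times = N), "+")
  dim(y) <- d
  list(y = y, xhat = xhat, ivar = ivar, rm = rm, rv = rv, dims = d)
}

bn_bwd <- function(cache, gamma, dy) {
  d <- cache$dims
  C <- d[3L]; N <- d[4L]
  dym <- matrix(dy, d[1L] * d[2L], C * N)
  xhat <- cache$xhat
  n_eff <- d[1L] * d[2L] * N
  sum_dy <- rowSums(matrix(.colSums(dym, nrow(dym), ncol(dym)), C, N))
  sum_dyx <- rowSums(matrix(.colSums(dym * xhat, nrow(dym), ncol(dym)), C, N))
  # dx = gamma * ivar / n * (n * dy - sum(dy) - xhat * sum(dy * xhat))
  scale <- gamma * cache$ivar / n_eff
  dx <- sweep(dym * n_eff, 2L, rep(sum_dy, times = N), "-") -
    sweep(xhat, 2L, rep(sum_dyx, times = N), "*")
  dx <- sweep(dx, 2L, rep(scale, times = N), "*")
  dim(dx) <- d
  list(dx = dx, dgamma = sum_dyx, dbeta = sum_dy)
}

maxpool_fwd <- function(x) cpp_maxpool2_fwd(x, dim(x))
maxpool_bwd <- function(cache_idx, dy, xdim) cpp_maxpool2_bwd(cache_idx, dy, xdim)

upsample_fwd <- function(x, target_hw) {
  cpp_upsample_bilinear_fwd(x, dim(x), as.integer(target_hw[1L]),
                            as.integer(target_hw[2L]))
}
upsample_bwd <- function(dy, source_hw) {
  cpp_upsample_bilinear_bwd(dy, dim(dy), as.integer(source_hw[1L]),
                            as.integer(source_hw[2L]))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

add_channel_bias <- function(x, b) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  m <- sweep(m, 2L, rep(b, times = d[4L]), "+")
  dim(m) <- d
  m
}

channel_sums <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  rowSums(matrix(.colSums(m, nrow(m), ncol(m)), d[3L], d[4L]))
}

# broadcast a single-channel gate over C channels
gate_mul <- function(x, g) {
  x * g[, , rep(1L, dim(x)[3L]), , drop = FALSE]
}

# sum over channels of an elementwise product, keeping one channel
reduce_channels <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L], 1L, d[4L]))
  for (n in seq_len(d[4L])) {
    acc <- x[, , 1L, n]
    if (d[3L] > 1L) for (c in 2:d[3L]) acc <- acc + x[, , c, n]
    out[, , 1L, n] <- acc
  }
  out
}
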