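test_that("zero-padding frames the image without altering its content", {
  img <- array(1, c(4, 4, 3))
  expect_identical(zero_pad_input(img, 0L), img)
  p <- zero_pad_input(matrix(1, 4, 4), 2L)
  expect_identical(dim(p), c(6L, 6L))
  expect_true(all(p[c(1, 6), ] == 0) && all(p[, c(1, 6)] == 0))
  expect_true(all(p[2:5, 2:5] == 1))
  set.seed(8)
  x <- array(runif(5 * 7 * 3), c(5, 7, 3))
  expect_equal(sum(zero_pad_input(x, 4L)), sum(x))
  expect_error(zero_pad_input(x, 3L), "even")
})

test_that("spatial attention reduces to known closed forms", {
  set.seed(9)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  # zero conv weights -> sigmoid(0) = 0.5 -> output is half the input
  z <- spatial_attention(x, array(0, c(7, 7, 2, 1)), 0)
  expect_equal(z$output, x / 2, tolerance = 1e-12)
  expect_true(all(z$attention == 0.5))
  # constant input -> pooled maps constant -> spatially constant attention
  # away from the zero-padded convolution border (7x7 kernel: 3-px frame)
  xc <- array(0.3, c(16, 16, 3))
  set.seed(10)
  w <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  zc <- spatial_attention(xc, w, 0.1)
  expect_true(all(zc$output >= 0))
  inner <- zc$output[5:12, 5:12, 1]
  expect_lt(diff(range(inner)), 1e-12)
})

test_that("spatial attention matches the explicit-loop oracle", {
  set.seed(11)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  w <- array(rnorm(7 * 7 * 2, sd = 0.3), c(7, 7, 2, 1))
  b <- 0.2
  res <- spatial_attention(x, w, b)
  pooled <- array(0, c(8, 8, 2))
  pooled[, , 1] <- apply(x, c(1, 2), max)
  pooled[, , 2] <- apply(x, c(1, 2), mean)
  gate <- oracle_sigmoid(oracle_conv(pooled, w, b)[, , 1])
  expected <- x * array(gate, c(8, 8, 3))
  expect_equal(res$output, expected, tolerance = 1e-5)
  expect_true(all(res$attention > 0 & res$attention < 1))
})

test_that("the additive attention gate saturates and matches its oracle", {
  ce <- 2L; cd <- 2L; ci <- 2L
  enc <- array(runif(4 * 4 * ce), c(4, 4, ce))
  dec <- array(runif(2 * 2 * cd), c(2, 2, cd))
  wz <- aam_weights(ce, cd, ci, seed = 5)
  # all-zero gate parameters -> gate = sigmoid(0) = 0.5
  w0 <- wz
  w0$w1[] <- 0; w0$w2[] <- 0; w0$b[] <- 0; w0$psi_w[] <- 0; w0$psi_b <- 0
  r0 <- additive_attention_gate(enc, dec, w0)
  expect_true(all(abs(r0$gate - 0.5) < 1e-12))
  expect_equal(r0$output[, , 1:ce], enc / 2, tolerance = 1e-12)
  # large shared bias with a pass-through projection saturates the gate
  wsat <- w0
  wsat$b[] <- 20; wsat$psi_w[] <- 1 / ci
  rsat <- additive_attention_gate(enc, dec, wsat)
  expect_true(all(rsat$gate > 0.9999))
  expect_equal(rsat$output[, , 1:ce], enc * rsat$gate[1, 1],
               tolerance = 1e-4)
  # full oracle on tiny volumes with fixed random weights
  set.seed(12)
  r <- additive_attention_gate(enc, dec, wz)
  up <- array(0, c(4, 4, cd))
  for (c in seq_len(cd)) up[, , c] <- oracle_upsample2(dec[, , c], 4L, 4L)
  convd <- oracle_conv(up, wz$wd)
  # inference-mode batch norm with fresh statistics: (x - 0)/sqrt(1 + eps)
  bn <- convd / sqrt(1 + 1e-5)
  proc <- pmax(bn, 0)
  pre <- oracle_conv(enc, wz$w1) + oracle_conv(proc, wz$w2)
  for (c in seq_len(ci)) pre[, , c] <- pre[, , c] + wz$b[c]
  gate <- oracle_sigmoid(oracle_conv(pmax(pre, 0), wz$psi_w, wz$psi_b)[, , 1])
  expect_equal(r$gate, gate, tolerance = 1e-5)
  expect_equal(r$output[, , 1:ce], enc * array(gate, c(4, 4, ce)),
               tolerance = 1e-5)
  expect_equal(r$output[, , ce + seq_len(cd)], proc, tolerance = 1e-5)
  expect_error(additive_attention_gate(enc, array(0, c(3, 3, cd)), wz),
               "half the encoder")
})

test_that("parameter counts reproduce the reference model sizes", {
  unet <- build_model(model_config(depth = 5, base_channels = 64))
  expect_identical(round(count_parameters(unet) / 1e6, 1), 17.3)
  reduced <- build_model(model_config(depth = 5, base_channels = 32))
  expect_identical(round(count_parameters(reduced) / 1e6, 1), 4.3)
  attn <- build_model(model_config(depth = 5, base_channels = 32,
                                   use_spatial_attention = TRUE,
                                   use_additive_attention = TRUE))
  expect_identical(round(count_parameters(attn) / 1e6, 1), 5.2)
  padded <- build_model(model_config(depth = 5, base_channels = 32,
                                     use_spatial_attention = TRUE,
                                     use_additive_attention = TRUE,
                                     pad_Z = 32))
  expect_identical(count_parameters(padded), count_parameters(attn))
})

test_that("halving the channels quarters the parameter count", {
  for (base in c(16L, 64L)) {
    big <- count_parameters(build_model(model_config(depth = 5, base_channels = base)))
    small <- count_parameters(build_model(model_config(depth = 5, base_channels = base %/% 2L)))
    expect_gt(small / big, 0.235)
    expect_lt(small / big, 0.265)
  }
})

test_that("the attention modules add about 0.9 M parameters to the reduced model", {
  n_red <- count_parameters(build_model(model_config(depth = 5, base_channels = 32)))
  n_attn <- count_parameters(build_model(model_config(depth = 5, base_channels = 32,
                                                      use_spatial_attention = TRUE,
                                                      use_additive_attention = TRUE)))
  expect_gt(n_attn - n_red, 0.75e6)
  expect_lt(n_attn - n_red, 1.05e6)
})

test_that("unit parameter counts are exact", {
  # single 3x3 conv with bias: 9 + 1
  cfg <- model_config(depth = 2, base_channels = 1)
  m <- build_model(cfg)
  expect_identical(length(m$params$out$w) + length(m$params$out$b),
                   1L * 2L + 2L) # 1x1 conv 1->2 with bias
  # batch norm holds 2C trainable scalars
  expect_identical(length(m$params$enc[[1]]$g1) + length(m$params$enc[[1]]$b1), 2L)
})

test_that("padding is weight-neutral: identical parameters at identical seeds", {
  cfg0 <- model_config(depth = 3, base_channels = 8,
                       use_spatial_attention = TRUE,
                       use_additive_attention = TRUE, pad_Z = 0)
  cfg32 <- model_config(depth = 3, base_channels = 8,
                        use_spatial_attention = TRUE,
                        use_additive_attention = TRUE, pad_Z = 32)
  m0 <- build_model(cfg0, seed = 77)
  m32 <- build_model(cfg32, seed = 77)
  expect_identical(m0$params, m32$params)
})

test_that("the network maps (H+Z)x(W+Z)x3 to (H+Z)x(W+Z)x2", {
  for (case in list(list(hw = c(16L, 24L), Z = 0L), list(hw = c(16L, 16L), Z = 8L))) {
    cfg <- model_config(depth = 3, base_channels = 4,
                        use_spatial_attention = TRUE,
                        use_additive_attention = TRUE, pad_Z = case$Z)
    m <- build_model(cfg, seed = 1)
    x <- array(runif(prod(case$hw + case$Z) * 3), c(case$hw + case$Z, 3, 1))
    y <- skintex:::unet_forward(m, x)$y
    expect_identical(dim(y), c(case$hw + case$Z, 2L, 1L))
  }
  cfg <- model_config(depth = 4, base_channels = 4)
  m <- build_model(cfg)
  bad <- array(0, c(12, 12, 3, 1)) # 12 not divisible by 8
  expect_error(skintex:::unet_forward(m, bad), "divisible")
})

test_that("attention gates stay strictly inside (0, 1) on random inputs", {
  cfg <- model_config(depth = 3, base_channels = 4,
                      use_spatial_attention = TRUE,
                      use_additive_attention = TRUE)
  m <- build_model(cfg, seed = 3)
  set.seed(13)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  fwd <- skintex:::unet_forward(m, x, keep_cache = TRUE)
  g_sa <- fwd$cache$sa$g
  expect_true(all(g_sa > 0 & g_sa < 1))
  for (lev in fwd$cache$dec) {
    if (!is.null(lev$aam)) {
      expect_true(all(lev$aam$g > 0 & lev$aam$g < 1))
    }
  }
})

test_that("transposed-convolution upsampling is available and consistent", {
  cfg <- model_config(depth = 3, base_channels = 4,
                      upsample_mode = "transposed_conv")
  m <- build_model(cfg, seed = 2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y <- skintex:::unet_forward(m, x)$y
  expect_identical(dim(y), c(16L, 16L, 2L, 1L))
  # the classic full-width transposed-conv network is larger than the
  # halved-bottleneck bilinear variant
  n_t <- count_parameters(build_model(model_config(depth = 5, base_channels = 64,
                                                   upsample_mode = "transposed_conv")))
  n_b <- count_parameters(build_model(model_config(depth = 5, base_channels = 64)))
  expect_gt(n_t, n_b)
})

test_that("model printing and summary report the parameter count", {
  m <- build_model(model_config(depth = 2, base_channels = 2), seed = 1)
  expect_output(print(m), "skin_unet")
  expect_output(df <- summary(m), "trainable parameters")
  expect_identical(sum(df$params), as.numeric(count_parameters(m)))
})
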