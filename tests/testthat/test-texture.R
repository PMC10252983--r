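test_that("grayscale conversion uses the luma weights", {
  white <- array(1, c(4, 4, 3))
  expect_equal(to_grayscale(white), matrix(1, 4, 4))
  green <- array(0, c(4, 4, 3)); green[, , 2] <- 1
  expect_equal(to_grayscale(green), matrix(0.587, 4, 4))
  set.seed(1)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  manual <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  expect_equal(to_grayscale(img), manual, tolerance = 1e-12)
  expect_error(to_grayscale(matrix(0, 4, 4)), "3-channel")
})

test_that("Gaussian blur matches the dense reflective-border oracle", {
  set.seed(2)
  x <- matrix(runif(19 * 23), 19, 23)
  expect_equal(gaussian_blur(x, 2), oracle_blur(x, 2), tolerance = 1e-12)
  expect_equal(gaussian_blur(x, 0.8), oracle_blur(x, 0.8), tolerance = 1e-12)
  # constants are invariant
  expect_equal(gaussian_blur(matrix(0.4, 9, 9), 3), matrix(0.4, 9, 9),
               tolerance = 1e-12)
})

test_that("wrinkle texture map has the closed form 255/(1+c) on constants", {
  for (c in c(0, 0.25, 0.5, 1)) {
    tm <- wrinkle_texture_map(matrix(c, 17, 17), sigma = 3)
    expect_equal(max(abs(unclass(tm) - 255 / (1 + c))), 0, tolerance = 1e-9)
  }
  expect_error(wrinkle_texture_map(matrix(0.5, 8, 8), sigma = 0), "positive")
})

test_that("wrinkle texture map highlights a dark pixel on bright background", {
  img <- matrix(0.8, 33, 33)
  img[17, 17] <- 0
  tm <- wrinkle_texture_map(img, sigma = 2)
  expect_equal(unclass(tm)[17, 17], 255) # I = 0 -> T = 255 exactly
  blur <- oracle_blur(img, 2)
  expected <- pmin(pmax((1 - img / (1 + blur)) * 255, 0), 255)
  expect_equal(unclass(tm), expected, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(attr(tm, "feature_class"), "wrinkle")
})

test_that("pyramid Reduce/Expand match the explicit-loop construction", {
  set.seed(3)
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  pyr <- build_pyramid(imp, 2L)
  expect_equal(pyr$laplacian[[1]],
               imp - oracle_expand(oracle_reduce(imp), c(16L, 16L)),
               tolerance = 1e-12)
  x <- matrix(runif(21 * 17), 21, 17) # odd sizes exercise ceil halving
  expect_equal(pyr_reduce(x), oracle_reduce(x), tolerance = 1e-12)
  r <- oracle_reduce(x)
  expect_equal(pyr_expand(r, dim(x)), oracle_expand(r, dim(x)),
               tolerance = 1e-12)
})

test_that("pyramid of a constant image has all-zero band-pass levels", {
  pyr <- build_pyramid(matrix(0.3, 32, 32), 3L)
  for (l in pyr$laplacian) expect_lt(max(abs(l)), 1e-12)
})

test_that("the Laplacian pyramid reconstructs its input", {
  set.seed(4)
  for (d in list(c(32L, 32L), c(37L, 29L))) {
    x <- matrix(runif(prod(d)), d[1L], d[2L])
    pyr <- build_pyramid(x, 4L)
    expect_lt(max(abs(reconstruct_pyramid(pyr) - x)), 1e-6)
    # defining identity of level 0
    expect_equal(pyr$gaussian[[1]],
                 pyr$laplacian[[1]] + pyr_expand(pyr$gaussian[[2]], d),
                 tolerance = 1e-12)
  }
  expect_error(build_pyramid(matrix(0, 4, 4), 5L), "too small")
})

test_that("pore texture map thresholds the band-pass field", {
  expect_true(all(pore_texture_map(matrix(0.5, 32, 32), 0.01) == 0))
  set.seed(5)
  x <- matrix(runif(32 * 32, 0.4, 0.6), 32, 32)
  t_field <- pore_band_pass(x)
  expect_true(all(pore_texture_map(x, max(abs(t_field)) + 0.01) == 0))
  # a small dark pit produces a localized positive blob at the pit
  img <- matrix(0.7, 32, 32)
  for (di in -2:2) for (dj in -2:2) {
    img[16 + di, 16 + dj] <- img[16 + di, 16 + dj] -
      0.4 * exp(-(di^2 + dj^2) / (2 * 1.2^2))
  }
  tm <- pore_texture_map(img, 0.01)
  expect_gt(unclass(tm)[16, 16], 0)
  support <- which(unclass(tm) > 0, arr.ind = TRUE)
  # support is a small blob containing the pit center; the expanded level-1
  # band contributes a ring of up to ~6 px radius around a point feature
  expect_lte(max(abs(support[, 1] - 16)), 8)
  expect_lte(max(abs(support[, 2] - 16)), 8)
  # band-pass field itself matches the loop oracle
  pyr_l0 <- img - oracle_expand(oracle_reduce(img), dim(img))
  g1 <- oracle_reduce(img)
  l1 <- g1 - oracle_expand(oracle_reduce(g1), dim(g1))
  expect_equal(pore_band_pass(img), -pyr_l0 + oracle_expand(l1, dim(img)),
               tolerance = 1e-12)
  expect_error(pore_texture_map(img, -0.1), ">= 0")
})

test_that("raising the pore threshold never grows the support", {
  set.seed(6)
  s <- generate_scene(fixture_scene_spec(seed = 31L))
  g <- to_grayscale(s$image)
  prev <- NULL
  for (th in c(0.005, 0.01, 0.02, 0.05, 0.1)) {
    sup <- unclass(pore_texture_map(g, th)) > 0
    if (!is.null(prev)) expect_false(any(sup & !prev))
    prev <- sup
  }
})

test_that("ground-truth composition masks the texture exactly", {
  set.seed(7)
  tex <- matrix(runif(20 * 20, 0, 255), 20, 20)
  ann <- matrix(runif(20 * 20) < 0.3, 20, 20)
  gt <- compose_ground_truth(tex, ann)
  expect_equal(gt[ann], tex[ann])
  expect_true(all(gt[!ann] == 0))
  expect_equal(compose_ground_truth(tex, matrix(TRUE, 20, 20)), tex)
  expect_true(all(compose_ground_truth(tex, matrix(FALSE, 20, 20)) == 0))
  checker <- outer(1:20, 1:20, function(i, j) (i + j) %% 2 == 0)
  gt2 <- compose_ground_truth(matrix(100, 20, 20), checker)
  expect_setequal(unique(as.numeric(gt2)), c(0, 100))
  expect_error(compose_ground_truth(tex, ann[1:10, ]), "dimensions")
})

test_that("texture filters enhance the features they target", {
  s <- generate_scene(fixture_scene_spec(seed = 17L))
  g <- to_grayscale(s$image)
  tw <- unclass(wrinkle_texture_map(g))
  expect_gt(mean(tw[s$fine_wrinkle_mask]), mean(tw))
  tp <- unclass(pore_texture_map(g))
  expect_gt(mean(tp[s$fine_pore_mask]), mean(tp))
  gt <- make_ground_truth(s)
  expect_true(all(gt$wrinkle[!s$coarse_wrinkle_annotation] == 0))
  expect_true(all(gt$pore[!s$coarse_pore_annotation] == 0))
  expect_true(all(gt$wrinkle >= 0 & gt$wrinkle <= 255))
  expect_true(all(gt$pore >= 0 & gt$pore <= 255))
})
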