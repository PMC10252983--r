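test_that("Frangi vesselness vanishes on uniform images and wrong polarity", {
  u <- matrix(0.6, 32, 32)
  expect_true(all(frangi_vesselness(u) == 0))
  expect_false(any(frangi_wrinkle_detect(u)))
  # dark line, bright-ridge polarity -> sign gate kills the response on the
  # line itself and leaves the flat background silent (the bright flanks of a
  # dark bar do respond by design, so they are excluded)
  img <- matrix(0.8, 48, 48)
  img[24:26, ] <- 0.3
  p_bright <- frangi_params(polarity = "bright_ridge", binarize_threshold = 0.01)
  det_bright <- frangi_wrinkle_detect(img, p_bright)
  expect_false(any(det_bright[24:26, ]))
  expect_false(any(det_bright[2:10, ]))
  p_dark <- frangi_params(binarize_threshold = 0.01)
  det_dark <- frangi_wrinkle_detect(img, p_dark)
  expect_true(any(det_dark[24:26, ]))
  expect_error(frangi_params(scales = numeric(0)), "non-empty")
  expect_error(frangi_params(beta = 0), "> 0")
})

test_that("Frangi response peaks on the centerline of a dark line", {
  img <- matrix(0.8, 64, 64)
  img[31:33, ] <- 0.3 # horizontal dark line of width 3, center row 32
  v <- frangi_vesselness(img, frangi_params(scales = c(1, 2, 3)))
  for (j in seq(8, 56, by = 8)) {
    expect_equal(which.max(v[, j]), 32L)
  }
  # direction of curvature agrees with a direct finite-difference Hessian:
  # the second derivative across the line is positive at its center
  hs <- oracle_hessian(gaussian_blur(img, 2))
  expect_true(all(hs$hyy[32, 8:56] > 0))
})

test_that("adding a Frangi scale never decreases the response", {
  s <- generate_scene(fixture_scene_spec(seed = 19L))
  g <- to_grayscale(s$image)
  v1 <- frangi_vesselness(g, frangi_params(scales = c(1, 2)))
  v2 <- frangi_vesselness(g, frangi_params(scales = c(1, 2, 3)))
  expect_true(all(v2 >= v1 - 1e-12))
})

test_that("vesselness commutes with 90-degree rotation", {
  s <- generate_scene(fixture_scene_spec(seed = 29L))
  g <- to_grayscale(s$image)
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  v <- frangi_vesselness(g)
  vr <- frangi_vesselness(rot90(g))
  inner <- 5:(nrow(g) - 4)
  expect_lt(max(abs(rot90(v)[inner, inner] - vr[inner, inner])), 1e-6)
})

test_that("classical pore detection finds isolated pits and filters by area", {
  img <- matrix(0.7, 60, 60)
  centers <- expand.grid(r = c(12, 30, 48), c = c(12, 30, 48))
  for (q in seq_len(nrow(centers))) {
    for (di in -2:2) for (dj in -2:2) {
      r <- centers$r[q] + di; c <- centers$c[q] + dj
      img[r, c] <- img[r, c] - 0.35 * exp(-(di^2 + dj^2) / (2 * 1.1^2))
    }
  }
  params <- pore_baseline_params(highpass_sigma = 3, k = 2,
                                 opening_radius = 0, min_area = 1,
                                 max_area = 100)
  mask <- pore_detect_classical(img, params)
  expect_identical(oracle_component_count(mask), 9L)
  # a dominating min_area filter removes everything
  strict <- pore_baseline_params(highpass_sigma = 3, k = 2,
                                 opening_radius = 0, min_area = 500,
                                 max_area = 1000)
  expect_false(any(pore_detect_classical(img, strict)))
  # degenerate input: uniform image -> documented empty-mask path
  expect_false(any(pore_detect_classical(matrix(0.5, 32, 32), params)))
  expect_error(pore_baseline_params(k = 1), ">= 2")
  expect_error(pore_baseline_params(min_area = 10, max_area = 1), "<=")
})

test_that("pore baseline is deterministic and respects the ROI", {
  s <- generate_scene(fixture_scene_spec(seed = 37L))
  g <- to_grayscale(s$image)
  m1 <- pore_detect_classical(g)
  m2 <- pore_detect_classical(g)
  expect_identical(m1, m2)
  roi <- s$zones$pore_zone
  m_roi <- pore_detect_classical(g, roi = roi)
  expect_false(any(m_roi & !roi))
})

test_that("the classical pore baseline fires on distractor texture that the trained network rejects", {
  ds <- fixture_dataset()
  fit <- trained_proposed_model()
  baseline_params <- pore_baseline_params(highpass_sigma = 3)
  baseline_distractor_px <- 0L
  network_distractor_px <- 0L
  for (s in ds$val) {
    g <- to_grayscale(s$image)
    outside <- !(s$zones$wrinkle_zone | s$zones$pore_zone)
    # distractor support: markedly dark pixels outside both zones
    distractor_px <- outside & (g < gaussian_blur(g, 4) - 0.1)
    base_mask <- pore_detect_classical(g, baseline_params)
    baseline_distractor_px <- baseline_distractor_px +
      sum(base_mask & distractor_px)
    pred <- predict(fit$model, s$image)
    net_mask <- binarize(pred[, , 2L], fit$thresholds[["pore"]])
    network_distractor_px <- network_distractor_px +
      sum(net_mask & distractor_px)
  }
  # the high-pass pipeline cannot tell distractors from pores ...
  expect_gt(baseline_distractor_px, 0L)
  # ... while the position-aware network suppresses them
  expect_lt(network_distractor_px, baseline_distractor_px)
})
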