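# tiny architecture + scenes keep the optimizer unit tests fast
tiny_setup <- function(n = 4L, seed = 21L) {
  spec <- scene_spec(height = 32L, width = 32L, n_wrinkles = 1L, n_pores = 3L,
                     n_distractors = 1L, wrinkle_thickness_range = c(2, 3),
                     pore_radius_range = c(1.2, 1.8), pore_contrast = 0.45,
                     seed = 1L)
  ds <- generate_dataset(spec, n, seed = seed)
  list(ds = ds, gt = lapply(ds, make_ground_truth))
}

tiny_model <- function(Z = 0L, seed = 5L) {
  build_model(model_config(depth = 3L, base_channels = 6L, pad_Z = Z),
              seed = seed)
}

test_that("zero epochs leave the weights untouched with an empty history", {
  s <- tiny_setup()
  m <- tiny_model()
  before <- m$params
  fit <- train_model(m, s$ds, s$gt, train_config(epochs = 0L, seed = 1L))
  expect_identical(fit$history, numeric(0))
  expect_identical(fit$model$params, before)
})

test_that("a zero learning rate freezes the loss history", {
  s <- tiny_setup()
  fit <- train_model(tiny_model(), s$ds, s$gt,
                     train_config(epochs = 3L, learning_rate = 0,
                                  batch_size = 2L, seed = 2L),
                     shuffle = "fixed")
  expect_length(fit$history, 3L)
  expect_lt(diff(range(fit$history)), 1e-12)
})

test_that("training reduces the loss on a small synthetic set", {
  s <- tiny_setup(n = 6L)
  fit <- train_model(tiny_model(), s$ds, s$gt,
                     train_config(epochs = 8L, batch_size = 2L, seed = 3L))
  expect_lt(tail(fit$history, 1L), fit$history[1L])
})

test_that("central crops restrict the training grid", {
  s <- tiny_setup(n = 2L)
  m <- build_model(model_config(depth = 2L, base_channels = 4L), seed = 5L)
  fit <- train_model(m, s$ds, s$gt,
                     train_config(epochs = 1L, batch_size = 2L, seed = 1L,
                                  crop_size = c(16L, 16L)))
  expect_length(fit$history, 1L)
  expect_error(train_config(crop_size = c(0L, 16L)), "positive")
  big <- train_config(epochs = 1L, batch_size = 2L, seed = 1L,
                      crop_size = c(64L, 64L))
  expect_error(train_model(m, s$ds, s$gt, big), "exceeds")
})

test_that("training is deterministic given its seeds", {
  s <- tiny_setup()
  f1 <- train_model(tiny_model(seed = 9L), s$ds, s$gt,
                    train_config(epochs = 2L, batch_size = 2L, seed = 4L))
  f2 <- train_model(tiny_model(seed = 9L), s$ds, s$gt,
                    train_config(epochs = 2L, batch_size = 2L, seed = 4L))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("prediction returns a two-channel map of the input size", {
  s <- tiny_setup(n = 2L)
  for (Z in c(0L, 4L)) {
    m <- tiny_model(Z = Z)
    p <- predict(m, s$ds[[1L]]$image)
    expect_identical(dim(p), c(32L, 32L, 2L))
    expect_identical(p, predict(m, s$ds[[1L]]$image)) # bit-identical repeat
  }
  m <- tiny_model(seed = 31L)
  p0 <- predict(m, s$ds[[1L]]$image)
  fit <- train_model(m, s$ds, s$gt,
                     train_config(epochs = 2L, batch_size = 2L, seed = 5L))
  expect_gt(max(abs(predict(fit$model, s$ds[[1L]]$image) - p0)), 0)
})

test_that("binarize applies a strict threshold", {
  m <- matrix(c(0, 50, 128, 200), 2, 2)
  expect_identical(binarize(m, 100), m > 100)
  expect_true(all(binarize(m, -1)))
  expect_false(any(binarize(m, 300)))
  expect_equal(as.numeric(binarize(m, 100)), c(0, 0, 1, 1))
})

test_that("IoU follows the set definition with documented empty conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1] <- TRUE
  expect_identical(iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 4] <- TRUE
  expect_identical(iou(a, b), 0)
  t6 <- matrix(FALSE, 4, 4); t6[1:4, 1] <- TRUE
  p6 <- matrix(FALSE, 4, 4); p6[3:4, 1] <- TRUE; p6[3:4, 2] <- TRUE
  expect_equal(iou(t6, p6), 2 / 6)
  empty <- matrix(FALSE, 4, 4)
  expect_identical(iou(empty, empty), 1)
  expect_identical(iou(a, empty), 0)
  expect_identical(iou(a, b), iou(b, a))
  expect_error(iou(a, matrix(FALSE, 3, 3)), "identical dimensions")
})

test_that("pooled IoU equals brute-force pooled counting", {
  s <- tiny_setup(n = 3L)
  m <- tiny_model(seed = 12L)
  th <- c(wrinkle = 64, pore = 32)
  rep <- iou_report(m, s$ds, th, ground_truth = s$gt)
  inter <- c(0, 0); uni <- c(0, 0)
  for (i in seq_along(s$ds)) {
    pred <- predict(m, s$ds[[i]]$image)
    pw <- pred[, , 1L] > th[["wrinkle"]]; tw <- s$gt[[i]]$wrinkle > th[["wrinkle"]]
    pp <- pred[, , 2L] > th[["pore"]]; tp <- s$gt[[i]]$pore > th[["pore"]]
    inter <- inter + c(sum(pw & tw), sum(pp & tp))
    uni <- uni + c(sum(pw | tw), sum(pp | tp))
  }
  expect_equal(rep$iou_wrinkle, if (uni[1] == 0) 1 else inter[1] / uni[1])
  expect_equal(rep$iou_pore, if (uni[2] == 0) 1 else inter[2] / uni[2])
  expect_identical(nrow(rep$per_image), 3L)
  expect_true(all(rep$per_image$iou_wrinkle >= 0 & rep$per_image$iou_wrinkle <= 1))
})

test_that("a single-config ablation row is consistent with the model builder", {
  s <- tiny_setup(n = 4L)
  cfg <- model_config(depth = 3L, base_channels = 6L)
  ab <- run_ablation(list(tiny = cfg), s$ds[1:3], s$ds[4],
                     config = train_config(epochs = 2L, batch_size = 2L, seed = 6L),
                     init_seed = 6L)
  expect_identical(nrow(ab), 1L)
  expect_identical(ab$n_params, count_parameters(build_model(cfg)))
  ab2 <- run_ablation(list(tiny = cfg, tiny2 = cfg), s$ds[1:3], s$ds[4],
                      config = train_config(epochs = 2L, batch_size = 2L, seed = 6L),
                      init_seed = 6L)
  # identical configurations produce identical rows
  expect_equal(ab2[1L, -1L], ab2[2L, -1L], ignore_attr = TRUE)
})

test_that("positional learning suppresses pore false positives outside the butterfly zone", {
  ab <- ablation_fixture()
  rows <- ab$rows
  proposed <- which(rows == "proposed")
  reduced <- which(rows == "reduced")
  expect_lt(ab$median_fp_outside[proposed], ab$median_fp_outside[reduced])
})
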