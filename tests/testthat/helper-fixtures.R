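# Shared fixtures. The ablation fixture is expensive (it trains the four
# model variants over three seeds), so it is computed lazily once per test
# run and cached for every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

# study-conditions fixture scaled to desk size: 48 x 48 crops, features
# sized to the texture filters (pores of a few pixels, strokes 2-4 px thick)
fixture_scene_spec <- function(seed = 1L) {
  scene_spec(height = 48L, width = 48L, n_wrinkles = 2L, n_pores = 6L,
             n_distractors = 4L, wrinkle_thickness_range = c(2, 4),
             pore_radius_range = c(1.2, 2), pore_contrast = 0.45,
             seed = seed)
}

fixture_dataset <- function() {
  if (is.null(.fixture_cache$dataset)) {
    ds <- generate_dataset(fixture_scene_spec(), 15L, seed = 11L)
    .fixture_cache$dataset <- list(train = ds[1:10], val = ds[11:15])
  }
  .fixture_cache$dataset
}

# the desk-scale ablation: four model variants (full-width, half-width,
# half-width + attentions, half-width + attentions + zero-padding), depth 4
# so the padding fraction stays moderate, three seeds, fixed budget
ablation_fixture <- function() {
  if (is.null(.fixture_cache$ablation)) {
    ds <- fixture_dataset()
    configs <- ablation_configs(pad_Z = 8L, depth = 4L)
    runs <- lapply(c(301L, 302L, 303L), function(s) {
      run_ablation(configs, ds$train, ds$val,
                   config = train_config(epochs = 24L, batch_size = 2L,
                                         learning_rate = 1e-3, seed = s),
                   init_seed = s)
    })
    med <- function(col) {
      vapply(seq_len(4L), function(r) {
        stats::median(vapply(runs, function(a) a[[col]][r], numeric(1)))
      }, numeric(1))
    }
    .fixture_cache$ablation <- list(
      runs = runs,
      rows = runs[[1L]]$model,
      median_val_loss = med("val_loss"),
      median_iou_pore = med("iou_pore"),
      median_iou_wrinkle = med("iou_wrinkle"),
      median_fp_outside = med("fp_pore_outside_zone")
    )
  }
  .fixture_cache$ablation
}

# a small trained proposed-variant model for qualitative comparisons
trained_proposed_model <- function() {
  if (is.null(.fixture_cache$proposed)) {
    ds <- fixture_dataset()
    gtr <- lapply(ds$train, make_ground_truth)
    cfg <- model_config(depth = 4L, base_channels = 32L,
                        use_spatial_attention = TRUE,
                        use_additive_attention = TRUE, pad_Z = 8L)
    fit <- train_model(build_model(cfg, seed = 301L), ds$train, gtr,
                       train_config(epochs = 24L, batch_size = 2L,
                                    seed = 301L))
    gva <- lapply(ds$val, make_ground_truth)
    th <- select_thresholds(fit$model, ds$val, gva)
    .fixture_cache$proposed <- list(model = fit$model, thresholds = th,
                                    history = fit$history)
  }
  .fixture_cache$proposed
}
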