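#' Write a dataset of synthetic samples to disk
#'
#' Images are written as 8-bit PNG, masks and coarse annotations as 0/255
#' PNG; a JSON manifest records per-sample file paths, seeds and split
#' membership.
#'
#' @param samples List of `synthetic_sample` objects.
#' @param dir Output directory (created if missing).
#' @param split Optional list with integer vectors `train` and `val`.
#' @return Path of the manifest file, invisibly.
#' @export
write_dataset <- function(samples, dir, split = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    base <- sprintf("sample_%03d", i)
    paths <- c(
      image = file.path(dir, paste0(base, "_image.png")),
      fine_wrinkle = file.path(dir, paste0(base, "_fine_wrinkle.png")),
      fine_pore = file.path(dir, paste0(base, "_fine_pore.png")),
      coarse_wrinkle = file.path(dir, paste0(base, "_coarse_wrinkle.png")),
      coarse_pore = file.path(dir, paste0(base, "_coarse_pore.png"))
    )
    write_image(s$image, paths[["image"]])
    write_mask(s$fine_wrinkle_mask, paths[["fine_wrinkle"]])
    write_mask(s$fine_pore_mask, paths[["fine_pore"]])
    write_mask(s$coarse_wrinkle_annotation, paths[["coarse_wrinkle"]])
    write_mask(s$coarse_pore_annotation, paths[["coarse_pore"]])
    membership <- if (is.null(split)) NA_character_
      else if (i %in% split$train) "train"
      else if (i %in% split$val) "val" else NA_character_
    rel <- basename(paths)
    names(rel) <- names(paths) # basename() drops names
    list(index = i, seed = s$spec$seed, split = membership,
         files = as.list(rel))
  })
  manifest <- file.path(dir, "dataset.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Default end-to-end pipeline configuration
#'
#' Small but complete settings: scene generation, ground-truth parameters,
#' model architecture and training budget. Every field can be overridden via
#' the `config` argument of [run_pipeline()] or a YAML file with the same
#' structure.
#'
#' @return Nested list of stage configurations.
#' @export
default_pipeline_config <- function() {
  list(
    scene = list(height = 48L, width = 48L, n_wrinkles = 2L, n_pores = 6L,
                 n_distractors = 4L, wrinkle_thickness_range = c(2, 4),
                 pore_radius_range = c(1.2, 2), pore_contrast = 0.45),
    data = list(n = 12L, n_train = 9L, seed = 7L, annotation_radius = 3),
    gt = list(sigma = 5, wrinkle_threshold = 64, pore_threshold = 4 / 255),
    model = list(depth = 4L, base_channels = 16L,
                 use_spatial_attention = TRUE,
                 use_additive_attention = TRUE, pad_Z = 8L,
                 upsample_mode = "bilinear_then_conv"),
    train = list(epochs = 4L, batch_size = 2L, learning_rate = 1e-3,
                 seed = 7L),
    eval = list(thresholds = NULL)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full generate / ground-truth / train / evaluate pipeline
#'
#' Executes the four stages with a shared configuration, writes all
#' artifacts (dataset PNGs, evaluation JSON, loss history) under `out_dir`
#' and returns a validated run manifest with config digests and file
#' hashes. Re-running with identical configuration reproduces identical
#' metric reports.
#'
#' @param config Nested list overriding [default_pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- stage_try("config", {
      if (!file.exists(config)) stop("config file not found: ", config)
      yaml::read_yaml(config)
    })
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  samples <- stage_try("generate", {
    spec <- do.call(scene_spec, cfg$scene)
    generate_dataset(spec, cfg$data$n, seed = cfg$data$seed,
                     annotation_radius = cfg$data$annotation_radius)
  })
  split <- stage_try("generate",
    split_dataset(cfg$data$n, cfg$data$n_train, cfg$data$seed))
  data_manifest <- stage_try("generate",
    write_dataset(samples, file.path(out_dir, "data"), split))

  gts <- stage_try("gt", lapply(samples, function(s)
    make_ground_truth(s, sigma = cfg$gt$sigma,
                      wrinkle_threshold = cfg$gt$wrinkle_threshold,
                      pore_threshold = cfg$gt$pore_threshold)))

  fit <- stage_try("train", {
    model <- build_model(do.call(model_config, cfg$model),
                         seed = cfg$train$seed)
    train_model(model, samples[split$train], gts[split$train],
                do.call(train_config, cfg$train))
  })
  history_path <- file.path(out_dir, "loss_history.json")
  jsonlite::write_json(fit$history, history_path, digits = NA)

  eval_res <- stage_try("eval", {
    th <- cfg$eval$thresholds
    if (is.null(th)) {
      th <- select_thresholds(fit$model, samples[split$val], gts[split$val])
    } else {
      th <- c(wrinkle = th[[1L]], pore = th[[2L]])
    }
    rep <- iou_report(fit$model, samples[split$val], th,
                      ground_truth = gts[split$val])
    list(thresholds = as.list(th),
         iou_wrinkle = rep$iou_wrinkle, iou_pore = rep$iou_pore,
         val_loss = validation_loss(fit$model, samples[split$val],
                                    gts[split$val]),
         per_image = rep$per_image)
  })
  eval_path <- file.path(out_dir, "eval.json")
  jsonlite::write_json(eval_res, eval_path, auto_unbox = TRUE, digits = NA)

  files <- c(data_manifest, history_path, eval_path)
  manifest <- list(
    version = as.character(utils::packageVersion("skintex")),
    config_hashes = lapply(cfg, config_digest),
    seeds = list(data = cfg$data$seed, train = cfg$train$seed),
    file_index = lapply(files, function(f) {
      list(path = f, role = c("dataset", "loss_history", "evaluation")[match(f, files)],
           md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  validate_manifest(manifest_path)
  invisible(manifest)
}

config_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate a run manifest
#'
#' Checks that every file the manifest references exists and that its MD5
#' digest still matches.
#'
#' @param path Path to a `manifest.json` written by [run_pipeline()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_manifest <- function(path) {
  man <- jsonlite::read_json(path)
  for (entry in man$file_index) {
    if (!file.exists(entry$path)) {
      stop("manifest references missing file: ", entry$path)
    }
    if (!identical(unname(tools::md5sum(entry$path)), entry$md5)) {
      stop("digest mismatch for ", entry$path)
    }
  }
  invisible(TRUE)
}
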