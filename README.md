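# skintex

Simultaneous segmentation of facial **wrinkles and pores** — the two
morphological (as opposed to colorimetric) skin features — from RGB facial
skin crops, together with everything needed to study the method without a
clinical dataset: a deterministic synthetic skin-image generator, classical
image-processing baselines, and IoU evaluation.

## The method

Three ideas are combined:

1. **Shape-prior ground truth.** Manual annotation of wrinkles and pores at
   pixel accuracy is impractical, so coarse (over-thick) annotations are
   refined by multiplication with per-class *texture maps*:

   - wrinkles: `T(x,y) = (1 − I(x,y) / (1 + (I ⋆ G_σ)(x,y))) · 255`, a
     Gaussian-normalized enhancer that lights up dark pixels lying on bright
     smoothed surroundings and rewards coherent elongated edges;
   - pores: `T(x,y) = t · 1{|t| > Th}` with `t = −L0 + Expand(L1)`, a
     band-pass of the Burt–Adelson Laplacian pyramid whose sign makes the
     few-pixel dark pits positive, hard-thresholded at `Th`.

   GT = texture map × coarse annotation, a *continuous* target with sharp
   boundaries.

2. **A compact attention U-Net.** An encoder–decoder with double
   3×3-conv/batch-norm/ReLU blocks predicts both classes at once (2-channel
   output, MSE loss against the continuous GT). The *reduced* variant halves
   all channel widths (≈ quarter the parameters). *Spatial attention*
   (channel-wise max+mean pooling → 7×7 conv → sigmoid) refines the
   bottleneck; *additive attention gates*
   `σ(ψ(ReLU(W₁k + W₂q + b)))` weight each skip connection, with the encoder
   features as key/value and the upsampled decoder features as query.

3. **Zero-padding as implicit positional encoding.** Wrinkles occur in the
   forehead/T/eye zones, pores in the butterfly (nose+cheek) zone. Padding
   the input with a frame of zeros (size `Z`) lets a CNN infer absolute
   position, so the network learns *where* each feature is plausible and
   suppresses detections in the wrong zone — at zero parameter cost.

Classical comparators are included: a multiscale Hessian-eigenvalue
(Frangi vesselness) wrinkle detector and a high-pass + k-means + morphology
pore detector, evaluated with `IoU(X, X̂) = |X ∩ X̂| / |X ∪ X̂|`.

The network engine (convolution, batch norm, pooling, bilinear upsampling —
forward and backward — plus Adam) is implemented in R on RcppArmadillo
GEMM kernels; no external deep-learning framework is used.

## Worked example

```r
library(skintex)

# a 48x48 synthetic skin crop: wrinkle strokes in the forehead/eye zones,
# pores in the butterfly zone, pore-like distractors outside both
spec <- scene_spec(height = 48, width = 48, n_wrinkles = 2, n_pores = 6,
                   n_distractors = 4, wrinkle_thickness_range = c(2, 4),
                   pore_radius_range = c(1.2, 2), pore_contrast = 0.45,
                   seed = 1)
ds <- generate_dataset(spec, 15, seed = 11)
train <- ds[1:10]; val <- ds[11:15]

# texture-refined continuous ground truth from the coarse annotations
gt_train <- lapply(train, make_ground_truth)

# the proposed model at desk scale: halved channels, both attentions, Z = 8
cfg <- model_config(depth = 4, base_channels = 32,
                    use_spatial_attention = TRUE,
                    use_additive_attention = TRUE, pad_Z = 8)
model <- build_model(cfg, seed = 301)
print(model)
#> <skin_unet: depth 4, base 32, spatial attention, additive attention, Z=8, 1.3 M parameters (1287912)>

fit <- train_model(model, train, gt_train,
                   train_config(epochs = 24, batch_size = 2, seed = 301))

gt_val <- lapply(val, make_ground_truth)
th <- select_thresholds(fit$model, val, gt_val)
iou_report(fit$model, val, th, ground_truth = gt_val)
#> <iou_report: wrinkle 0.8445, pore 0.4585 over 5 images>
```

The printed IoUs say that, after 24 epochs on ten images, the binarized
wrinkle prediction overlaps the binarized ground truth with IoU ≈ 0.84 and
the pore prediction with IoU ≈ 0.46 on the five held-out images. The same
pipeline with the plain reduced network (no attention, no padding) reaches a
markedly lower pore IoU and several times more pore false positives outside
the butterfly zone — the positional-learning effect the zero-padding is for.

The full-scale architectures are available unchanged: the four
standard variants and their trainable-parameter counts are

```r
sapply(ablation_configs(pad_Z = 32), function(cfg)
  round(count_parameters(build_model(cfg)) / 1e6, 1))
#>         unet      reduced reduced_attn     proposed
#>         17.3          4.3          5.2          5.2
```

## Command line

A thin CLI over the package functions is installed with the package:

```sh
Rscript inst/scripts/skintex generate --n 10 --seed 7 --out data/
Rscript inst/scripts/skintex gt --image img.png --out gt/
Rscript inst/scripts/skintex baseline frangi --image img.png --out mask.png
Rscript inst/scripts/skintex model-summary --depth 5 --base 64
Rscript inst/scripts/skintex pipeline --config pipeline.yaml --out run/
```
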