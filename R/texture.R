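#' Wrinkle texture map (Gaussian-normalized dark-edge enhancement)
#'
#' Per pixel, `T = (1 - I / (1 + I_blur)) * 255` where `I_blur` is the
#' Gaussian-filtered image (reflective borders). Dark pixels lying on bright
#' blurred surroundings yield high values, and the Gaussian smoothing of the
#' denominator rewards coherent elongated structures; output is clipped to
#' \[0, 255\]. The image must use the \[0, 1\] intensity convention so the
#' denominator stays in \[1, 2\] and the map can span the full \[0, 255\]
#' range. On a constant image `I = c` the map equals `255 / (1 + c)` exactly.
#'
#' @param gray Numeric matrix in \[0, 1\].
#' @param sigma Gaussian scale in pixels (> 0); the default of 5 px matches
#'   the width of typical wrinkle cross-sections at the working resolution.
#' @return A `texture_map` matrix in \[0, 255\] with attribute
#'   `feature_class = "wrinkle"`.
#' @export
wrinkle_texture_map <- function(gray, sigma = 5) {
  check_gray(gray)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  blur <- gaussian_blur(gray, sigma)
  tm <- (1 - gray / (1 + blur)) * 255
  tm <- pmin(pmax(tm, 0), 255)
  structure(tm, feature_class = "wrinkle", class = c("texture_map", class(tm)))
}

check_gray <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray)) {
    stop("expected a numeric grayscale matrix")
  }
  if (anyNA(gray) || any(!is.finite(gray))) stop("grayscale image contains non-finite values")
  if (min(gray) < -1e-9 || max(gray) > 1 + 1e-9) {
    stop("grayscale image must use the [0, 1] intensity convention")
  }
  invisible(gray)
}

# 5-tap binomial kernel (1, 4, 6, 4, 1) / 16 of the Burt-Adelson pyramid
pyramid_kernel <- function() c(1, 4, 6, 4, 1) / 16

#' Gaussian/Laplacian pyramid (Burt-Adelson construction)
#'
#' `Reduce` blurs with the separable 5-tap binomial kernel
#' `(1, 4, 6, 4, 1) / 16` (half-sample reflective borders) and keeps every
#' second pixel, so level `i` has dimensions `ceiling(dim(i - 1) / 2)`.
#' `Expand` zero-upsamples to a requested target size and blurs with the
#' same kernel at x4 gain, using whole-sample (reflect-101) borders so the
#' sample parity is preserved and constants are reproduced exactly. Band-pass levels satisfy
#' `laplacian[[i]] = gaussian[[i]] - expand(gaussian[[i + 1]])` exactly, so
#' the pyramid reconstructs the input to floating-point accuracy.
#'
#' @param gray Numeric matrix.
#' @param n_levels Number of Gaussian levels (>= 2).
#' @return An object of class `image_pyramid` with lists `gaussian`
#'   (`n_levels` matrices) and `laplacian` (`n_levels - 1` band-pass
#'   matrices).
#' @export
build_pyramid <- function(gray, n_levels = 3L) {
  if (!is.numeric(n_levels) || n_levels < 2L) stop("n_levels must be >= 2")
  n_levels <- as.integer(n_levels)
  g <- list(as.matrix(gray))
  for (i in seq_len(n_levels - 1L)) {
    cur <- g[[i]]
    if (nrow(cur) < 4L || ncol(cur) < 4L) {
      stop("image too small to build pyramid level ", i + 1L,
           " (level ", i, " is ", nrow(cur), "x", ncol(cur), ")")
    }
    g[[i + 1L]] <- pyr_reduce(cur)
  }
  lap <- vector("list", n_levels - 1L)
  for (i in seq_len(n_levels - 1L)) {
    lap[[i]] <- g[[i]] - pyr_expand(g[[i + 1L]], dim(g[[i]]))
  }
  structure(list(gaussian = g, laplacian = lap), class = "image_pyramid")
}

#' Pyramid Reduce: binomial blur then 2x decimation
#' @param x Numeric matrix.
#' @return Matrix of dimensions `ceiling(dim(x) / 2)`.
#' @export
pyr_reduce <- function(x) {
  b <- cpp_sepconv_reflect(as.matrix(x), pyramid_kernel())
  b[seq(1L, nrow(b), by = 2L), seq(1L, ncol(b), by = 2L), drop = FALSE]
}

#' Pyramid Expand: zero-insertion upsampling then binomial blur at x4 gain
#' @param x Numeric matrix.
#' @param target_dim Integer `(rows, cols)` of the output (must be compatible
#'   with one Reduce step, i.e. `ceiling(target_dim / 2) == dim(x)`).
#' @return Matrix of size `target_dim`.
#' @export
pyr_expand <- function(x, target_dim) {
  x <- as.matrix(x)
  td <- as.integer(target_dim)
  if (!identical(as.integer(ceiling(td / 2)), as.integer(dim(x)))) {
    stop("target_dim incompatible with Expand: ceiling(target_dim / 2) must equal dim(x)")
  }
  up <- matrix(0, td[1L], td[2L])
  up[seq(1L, td[1L], by = 2L), seq(1L, td[2L], by = 2L)] <- x
  # whole-sample (reflect-101) borders keep the sample/zero parity of the
  # upsampled grid, so Expand reproduces constants exactly
  4 * cpp_sepconv_reflect(up, pyramid_kernel(), whole_sample = TRUE)
}

#' Reconstruct the original image from a pyramid
#'
#' @param pyr An `image_pyramid`.
#' @return Matrix equal to the pyramid's input up to floating-point error.
#' @export
reconstruct_pyramid <- function(pyr) {
  stopifnot(inherits(pyr, "image_pyramid"))
  n <- length(pyr$gaussian)
  acc <- pyr$gaussian[[n]]
  for (i in rev(seq_len(n - 1L))) {
    acc <- pyr$laplacian[[i]] + pyr_expand(acc, dim(pyr$laplacian[[i]]))
  }
  acc
}

#' Pore texture map (Laplacian-pyramid band-pass with hard threshold)
#'
#' Computes `t = -L0 + Expand(L1)` from a 3-level Laplacian pyramid; the sign
#' is chosen so that pores, which are darker than their surroundings, come
#' out positive. Values with `|t| <= threshold` are zeroed (hard threshold),
#' and the surviving band-pass response is mapped affinely to \[0, 255\] via
#' `255 * clip(t, 0, t_max) / t_max`, which also zeroes negative (bright)
#' responses.
#'
#' @param gray Numeric matrix in \[0, 1\], large enough for a 3-level pyramid.
#' @param threshold Hard threshold on the band-pass amplitude (>= 0); default
#'   4/255 suppresses sensor-noise-level responses.
#' @param t_max Band-pass amplitude mapped to 255; fixed so the map scale does
#'   not depend on image content.
#' @return A `texture_map` matrix in \[0, 255\] with attribute
#'   `feature_class = "pore"`.
#' @export
pore_texture_map <- function(gray, threshold = 4 / 255, t_max = 0.25) {
  check_gray(gray)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single number >= 0")
  }
  t_field <- pore_band_pass(gray)
  keep <- abs(t_field) > threshold
  tm <- 255 * pmin(pmax(t_field, 0), t_max) / t_max
  tm[!keep] <- 0
  structure(tm, feature_class = "pore", class = c("texture_map", class(tm)))
}

#' Raw pore band-pass field `t = -L0 + Expand(L1)`
#'
#' @param gray Numeric matrix.
#' @return Matrix of signed band-pass amplitudes (positive at dark pits).
#' @export
pore_band_pass <- function(gray) {
  pyr <- build_pyramid(gray, 3L)
  -pyr$laplacian[[1L]] + pyr_expand(pyr$laplacian[[2L]], dim(pyr$laplacian[[1L]]))
}

#' Multiply a texture map with a coarse annotation mask
#'
#' The annotation acts as a 0/1 gate: output is identical to the texture map
#' inside the annotation and exactly zero outside, yielding continuous ground
#' truth with well-defined boundaries from over-thick manual labels.
#'
#' @param texture Numeric matrix (typically a `texture_map`).
#' @param annotation Logical or 0/1 matrix of the same size.
#' @return Numeric matrix.
#' @export
compose_ground_truth <- function(texture, annotation) {
  if (!identical(dim(texture), dim(annotation))) {
    stop("texture and annotation must have identical dimensions")
  }
  unclass(texture) * (annotation != 0)
}

#' Two-channel continuous ground truth for a synthetic sample
#'
#' Builds the wrinkle and pore texture maps from the sample's image,
#' thresholds the wrinkle map (values below `wrinkle_threshold` are zeroed
#' before masking) and multiplies each map with the corresponding coarse
#' annotation.
#'
#' @param sample A `synthetic_sample` (or any list with fields `image`,
#'   `coarse_wrinkle_annotation`, `coarse_pore_annotation`).
#' @param sigma Gaussian scale of the wrinkle map.
#' @param wrinkle_threshold Hard threshold on the wrinkle map (0-255 scale).
#' @param pore_threshold Hard threshold of the pore band-pass amplitude.
#' @return An object of class `ground_truth_map`: list with matrices
#'   `wrinkle` and `pore`, both in \[0, 255\] and zero outside the
#'   corresponding annotation.
#' @export
make_ground_truth <- function(sample, sigma = 5, wrinkle_threshold = 64,
                              pore_threshold = 4 / 255) {
  gray <- to_grayscale(sample$image)
  tw <- wrinkle_texture_map(gray, sigma = sigma)
  tw <- unclass(tw)
  tw[tw < wrinkle_threshold] <- 0
  tp <- pore_texture_map(gray, threshold = pore_threshold)
  structure(list(
    wrinkle = compose_ground_truth(tw, sample$coarse_wrinkle_annotation),
    pore = compose_ground_truth(tp, sample$coarse_pore_annotation)
  ), class = "ground_truth_map")
}
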