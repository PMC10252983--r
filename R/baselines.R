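#' Parameters of the Frangi vesselness wrinkle detector
#'
#' @param scales Gaussian standard deviations (pixels) probed by the filter;
#'   responses are maximized over scales.
#' @param beta Blobness sensitivity (> 0).
#' @param c Structureness sensitivity (> 0); the default of 0.08 suits images
#'   on the \[0, 1\] intensity scale.
#' @param polarity `"dark_ridge"` (wrinkles: dark lines on bright skin) or
#'   `"bright_ridge"`.
#' @param binarize_threshold Vesselness cutoff used by
#'   [frangi_wrinkle_detect()].
#' @return Object of class `frangi_params`.
#' @export
frangi_params <- function(scales = c(1, 2, 3), beta = 0.5, c = 0.08,
                          polarity = c("dark_ridge", "bright_ridge"),
                          binarize_threshold = 0.1) {
  polarity <- match.arg(polarity)
  if (length(scales) < 1L || any(scales <= 0)) {
    stop("scales must be a non-empty vector of positive values")
  }
  if (beta <= 0 || c <= 0) stop("beta and c must be > 0")
  structure(list(scales = as.numeric(scales), beta = beta, c = c,
                 polarity = polarity,
                 binarize_threshold = binarize_threshold),
            class = "frangi_params")
}

# scale-normalized Hessian of a Gaussian-smoothed image via central
# differences; returns list(hxx, hyy, hxy), each multiplied by s^2
hessian_at_scale <- function(gray, s) {
  g <- gaussian_blur(gray, s)
  h <- nrow(g); w <- ncol(g)
  # replicate borders for the finite differences
  gp <- rbind(g[1L, , drop = FALSE], g, g[h, , drop = FALSE])
  gp <- cbind(gp[, 1L, drop = FALSE], gp, gp[, w, drop = FALSE])
  ci <- 2:(h + 1L); cj <- 2:(w + 1L)
  hxx <- gp[ci, cj + 1L] - 2 * gp[ci, cj] + gp[ci, cj - 1L] # along columns (x)
  hyy <- gp[ci + 1L, cj] - 2 * gp[ci, cj] + gp[ci - 1L, cj] # along rows (y)
  hxy <- (gp[ci + 1L, cj + 1L] - gp[ci + 1L, cj - 1L] -
          gp[ci - 1L, cj + 1L] + gp[ci - 1L, cj - 1L]) / 4
  list(hxx = s^2 * hxx, hyy = s^2 * hyy, hxy = s^2 * hxy)
}

#' Multiscale Frangi vesselness response
#'
#' For each scale the Hessian eigenvalues are ordered `|l1| <= |l2|` and the
#' vesselness is `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with
#' `Rb = l1 / l2` and `S = sqrt(l1^2 + l2^2)`; responses whose `l2` sign
#' conflicts with the requested polarity are zeroed (dark ridges require
#' `l2 > 0`). The per-pixel response is the maximum over scales.
#'
#' @param gray Numeric matrix in \[0, 1\].
#' @param params A [frangi_params()].
#' @return Numeric matrix of vesselness values in \[0, 1\].
#' @export
frangi_vesselness <- function(gray, params = frangi_params()) {
  stopifnot(inherits(params, "frangi_params"))
  check_gray(gray)
  resp <- matrix(0, nrow(gray), ncol(gray))
  for (s in params$scales) {
    hs <- hessian_at_scale(gray, s)
    half_diff <- (hs$hxx - hs$hyy) / 2
    rad <- sqrt(half_diff^2 + hs$hxy^2)
    mu <- (hs$hxx + hs$hyy) / 2
    e1 <- mu + rad
    e2 <- mu - rad
    big_is_e1 <- abs(e1) >= abs(e2)
    l2 <- ifelse(big_is_e1, e1, e2)
    l1 <- ifelse(big_is_e1, e2, e1)
    rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
    s2 <- l1^2 + l2^2
    v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-s2 / (2 * params$c^2)))
    gate <- if (params$polarity == "dark_ridge") l2 > 0 else l2 < 0
    v[!gate] <- 0
    resp <- pmax(resp, v)
  }
  resp
}

#' Frangi-filter wrinkle detection
#'
#' Thresholds the multiscale vesselness response; optionally restricted to a
#' region of interest, mirroring evaluation protocols where the target area
#' is cropped in advance for classical filters.
#'
#' @param gray Numeric matrix in \[0, 1\].
#' @param params A [frangi_params()].
#' @param roi Optional logical matrix; detections outside it are discarded.
#' @return Logical wrinkle mask.
#' @export
frangi_wrinkle_detect <- function(gray, params = frangi_params(), roi = NULL) {
  mask <- frangi_vesselness(gray, params) > params$binarize_threshold
  if (!is.null(roi)) mask <- mask & (roi != 0)
  mask
}

#' Parameters of the classical pore detector
#'
#' @param highpass_sigma Gaussian scale (pixels) of the background estimate
#'   subtracted to form the high-pass residual.
#' @param k Number of k-means clusters on the residual values (>= 2).
#' @param opening_radius Disk radius of the morphological opening (0 skips
#'   it).
#' @param min_area,max_area Connected components outside this pixel-area
#'   range are removed.
#' @param seed Seed for the clustering initialization.
#' @return Object of class `pore_baseline_params`.
#' @export
pore_baseline_params <- function(highpass_sigma = 4, k = 2L,
                                 opening_radius = 1, min_area = 2,
                                 max_area = 200, seed = 0L) {
  if (k < 2L) stop("k must be >= 2")
  if (opening_radius < 0 || min_area < 0 || max_area < 0) {
    stop("radii and areas must be >= 0")
  }
  if (min_area > max_area) stop("min_area must be <= max_area")
  structure(list(highpass_sigma = highpass_sigma, k = as.integer(k),
                 opening_radius = opening_radius, min_area = min_area,
                 max_area = max_area, seed = as.integer(seed)),
            class = "pore_baseline_params")
}

#' Classical pore detection: high-pass, k-means, morphology
#'
#' The pipeline subtracts a Gaussian background estimate, clusters the
#' per-pixel residuals with k-means (fixed seed, capped iterations), keeps
#' the darkest-residual cluster, applies a disk opening and removes
#' connected components outside `[min_area, max_area]`. On a degenerate
#' residual (fewer distinct values than clusters, e.g. a uniform image) an
#' empty mask is returned.
#'
#' @param gray Numeric matrix in \[0, 1\].
#' @param params A [pore_baseline_params()].
#' @param roi Optional logical matrix restricting the analysis.
#' @return Logical pore mask.
#' @export
pore_detect_classical <- function(gray, params = pore_baseline_params(),
                                  roi = NULL) {
  stopifnot(inherits(params, "pore_baseline_params"))
  check_gray(gray)
  hp <- gray - gaussian_blur(gray, params$highpass_sigma)
  vals <- as.numeric(hp)
  if (length(unique(round(vals, 12))) < params$k) {
    return(matrix(FALSE, nrow(gray), ncol(gray))) # degenerate clustering input
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)
  km <- tryCatch(
    kmeans(vals, centers = params$k, iter.max = 100L, nstart = 3L),
    error = function(e) stop("pore baseline clustering failed: ",
                             conditionMessage(e)))
  darkest <- which.min(km$centers)
  mask <- matrix(km$cluster == darkest, nrow(gray), ncol(gray))
  if (params$opening_radius > 0 && any(mask)) {
    k <- disk_kernel(params$opening_radius)
    mask <- matrix(EBImage::imageData(EBImage::opening(EBImage::Image(mask * 1), k)) > 0.5,
                   nrow(gray), ncol(gray))
  }
  mask <- filter_components_by_area(mask, params$min_area, params$max_area)
  if (!is.null(roi)) mask <- mask & (roi != 0)
  mask
}

#' Remove connected components outside an area range
#'
#' @param mask Logical matrix.
#' @param min_area,max_area Inclusive pixel-area bounds.
#' @return Logical matrix.
#' @export
filter_components_by_area <- function(mask, min_area, max_area) {
  m <- mask != 0
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area & sizes <= max_area)
  matrix(lab %in% keep, nrow(m), ncol(m))
}
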