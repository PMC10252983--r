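#' Specification of a synthetic facial-skin scene
#'
#' Describes one generated skin crop: a smooth skin-like background carrying
#' dark curvilinear wrinkle strokes (forehead / eye zones), small dark pore
#' pits (butterfly zone) and pore-like distractor texture outside both zones.
#' The defaults emulate a 256x256 crop of a facial image that covers the
#' forehead, eye and butterfly regions.
#'
#' @param height,width Image size in pixels (>= 32).
#' @param background_mean Mean skin intensity in \[0, 1\].
#' @param background_smoothness Low-pass scale of the background texture, in
#'   pixels.
#' @param n_wrinkles Number of wrinkle strokes.
#' @param wrinkle_thickness_range `(min, max)` stroke thickness in pixels.
#' @param wrinkle_contrast Peak intensity drop of a stroke, in (0, 1].
#' @param n_pores Number of pore pits.
#' @param pore_radius_range `(min, max)` pore radius in pixels.
#' @param pore_contrast Peak intensity drop of a pore, in (0, 1].
#' @param n_distractors Number of pore-like dark spots placed outside both
#'   occurrence zones (and absent from every mask).
#' @param lighting_gradient Amplitude of a linear illumination ramp across the
#'   image (0 disables it).
#' @param noise_amplitude Standard deviation of the low-passed background
#'   texture.
#' @param seed Integer seed; identical specs generate bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 256L, width = 256L,
                       background_mean = 0.72, background_smoothness = 24,
                       n_wrinkles = 6L, wrinkle_thickness_range = c(2, 6),
                       wrinkle_contrast = 0.35,
                       n_pores = 40L, pore_radius_range = c(1.5, 3),
                       pore_contrast = 0.3,
                       n_distractors = 10L,
                       lighting_gradient = 0.06, noise_amplitude = 0.035,
                       seed = 1L) {
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    background_mean = background_mean,
    background_smoothness = background_smoothness,
    n_wrinkles = as.integer(n_wrinkles),
    wrinkle_thickness_range = as.numeric(wrinkle_thickness_range),
    wrinkle_contrast = wrinkle_contrast,
    n_pores = as.integer(n_pores),
    pore_radius_range = as.numeric(pore_radius_range),
    pore_contrast = pore_contrast,
    n_distractors = as.integer(n_distractors),
    lighting_gradient = lighting_gradient,
    noise_amplitude = noise_amplitude,
    seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$height < 32L || spec$width < 32L) {
    stop("scene_spec: height and width must be >= 32")
  }
  if (spec$n_wrinkles < 0L || spec$n_pores < 0L || spec$n_distractors < 0L) {
    stop("scene_spec: feature counts must be >= 0")
  }
  for (nm in c("wrinkle_contrast", "pore_contrast")) {
    v <- spec[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1) stop("scene_spec: ", nm, " must lie in (0, 1]")
  }
  for (nm in c("wrinkle_thickness_range", "pore_radius_range")) {
    v <- spec[[nm]]
    if (length(v) != 2L || any(v <= 0) || v[1] > v[2]) {
      stop("scene_spec: ", nm, " must be an ordered positive (min, max) pair")
    }
  }
  invisible(spec)
}

#' Default occurrence-zone layout
#'
#' Wrinkles concentrate in a forehead band (top 30% of the crop) plus two
#' 15% x 15% eye-corner boxes at the left and right edges at mid-height;
#' pores concentrate in a central butterfly box spanning 40% of the height
#' and 60% of the width.
#'
#' @param height,width Image size in pixels.
#' @return An object of class `zone_layout` with logical `wrinkle_zone` and
#'   `pore_zone` masks.
#' @export
default_zone_layout <- function(height, width) {
  h <- as.integer(height); w <- as.integer(width)
  wz <- matrix(FALSE, h, w)
  wz[seq_len(max(1L, floor(0.30 * h))), ] <- TRUE
  bh <- max(2L, floor(0.15 * h)); bw <- max(2L, floor(0.15 * w))
  r0 <- floor(h / 2 - bh / 2) + 1L
  wz[r0:(r0 + bh - 1L), 1:bw] <- TRUE
  wz[r0:(r0 + bh - 1L), (w - bw + 1L):w] <- TRUE
  pz <- matrix(FALSE, h, w)
  ph <- max(2L, floor(0.40 * h)); pw <- max(2L, floor(0.60 * w))
  pr0 <- floor(h / 2 - ph / 2) + 1L
  pc0 <- floor(w / 2 - pw / 2) + 1L
  pz[pr0:(pr0 + ph - 1L), pc0:(pc0 + pw - 1L)] <- TRUE
  zone_layout(wz, pz)
}

#' Construct a zone layout from explicit masks
#'
#' @param wrinkle_zone,pore_zone Logical matrices of identical size; the zones
#'   may overlap but neither may be empty.
#' @return An object of class `zone_layout`.
#' @export
zone_layout <- function(wrinkle_zone, pore_zone) {
  if (!identical(dim(wrinkle_zone), dim(pore_zone))) {
    stop("zone_layout: masks must have identical dimensions")
  }
  wz <- wrinkle_zone != 0
  pz <- pore_zone != 0
  if (!any(wz)) stop("zone_layout: wrinkle_zone is empty")
  if (!any(pz)) stop("zone_layout: pore_zone is empty")
  structure(list(wrinkle_zone = wz, pore_zone = pz), class = "zone_layout")
}

# half-width-at-half-maximum factor of a Gaussian profile: support is
# d < HWHM_FACTOR * sigma where the intensity drop exceeds half its peak
HWHM_FACTOR <- sqrt(2 * log(2))

# stamp an isotropic Gaussian pit into the drop field (combining by max) and
# return the updated state; support = pixels within `radius` of the center
stamp_pore <- function(drop, support, ci, cj, radius, contrast) {
  h <- nrow(drop); w <- ncol(drop)
  sigma <- radius / HWHM_FACTOR
  win <- ceiling(3 * sigma) + 1L
  ri <- max(1L, floor(ci - win)):min(h, ceiling(ci + win))
  rj <- max(1L, floor(cj - win)):min(w, ceiling(cj + win))
  d2 <- outer((ri - ci)^2, (rj - cj)^2, "+")
  local <- contrast * exp(-d2 / (2 * sigma^2))
  drop[ri, rj] <- pmax(drop[ri, rj], local)
  support[ri, rj] <- support[ri, rj] | (d2 < (HWHM_FACTOR * sigma)^2)
  list(drop = drop, support = support)
}

# sample a smooth stroke centerline: 3-5 control points joined by natural
# cubic splines, densely resampled; returns an m x 2 matrix of (row, col)
sample_stroke <- function(ci, cj, extent) {
  np <- sample(3:5, 1L)
  ang <- runif(1L, 0, 2 * pi)
  # loose random walk around a main direction
  pts <- matrix(0, np, 2L)
  pts[1L, ] <- c(ci, cj)
  for (p in 2:np) {
    ang <- ang + runif(1L, -0.7, 0.7)
    step <- runif(1L, 0.5, 1) * extent / (np - 1L)
    pts[p, ] <- pts[p - 1L, ] + step * c(sin(ang), cos(ang))
  }
  t0 <- seq_len(np)
  tt <- seq(1, np, by = 0.02)
  cbind(spline(t0, pts[, 1L], xout = tt)$y,
        spline(t0, pts[, 2L], xout = tt)$y)
}

# distance from each pixel of a window to a polyline (vertex distance on a
# densely resampled curve is accurate to half the resampling step)
stamp_stroke <- function(drop, support, curve, thickness, contrast, h, w) {
  sigma <- (thickness / 2) / HWHM_FACTOR
  win <- ceiling(3 * sigma) + 2L
  ri <- max(1L, floor(min(curve[, 1L])) - win):min(h, ceiling(max(curve[, 1L])) + win)
  rj <- max(1L, floor(min(curve[, 2L])) - win):min(w, ceiling(max(curve[, 2L])) + win)
  # resample curve to ~0.25 px spacing for an accurate distance field
  seg <- sqrt(diff(curve[, 1L])^2 + diff(curve[, 2L])^2)
  arc <- c(0, cumsum(seg))
  n_res <- max(2L, ceiling(arc[length(arc)] / 0.25))
  s <- seq(0, arc[length(arc)], length.out = n_res)
  cr <- approx(arc, curve[, 1L], xout = s)$y
  cc <- approx(arc, curve[, 2L], xout = s)$y
  gi <- rep(ri, times = length(rj))
  gj <- rep(rj, each = length(ri))
  dmin <- rep(Inf, length(gi))
  for (kchunk in split(seq_len(n_res), ceiling(seq_len(n_res) / 256))) {
    d2 <- outer(gi, cr[kchunk], "-")^2 + outer(gj, cc[kchunk], "-")^2
    dmin <- pmin(dmin, sqrt(.rowMins(d2)))
  }
  local <- matrix(contrast * exp(-dmin^2 / (2 * sigma^2)), length(ri), length(rj))
  drop[ri, rj] <- pmax(drop[ri, rj], local)
  sup <- matrix(dmin < HWHM_FACTOR * sigma, length(ri), length(rj))
  support[ri, rj] <- support[ri, rj] | sup
  list(drop = drop, support = support)
}

.rowMins <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmin(out, m[, j])
  out
}

# rejection-sample a feature center inside `allowed` (logical matrix);
# centers must keep a gap of >= 2 px between supports: distance to center k
# at least radius + radii[k] + 2
place_center <- function(allowed_idx, h, centers, radii, radius, what,
                         zone_name) {
  for (try in seq_len(600L)) {
    pick <- allowed_idx[sample.int(length(allowed_idx), 1L)]
    ci <- ((pick - 1L) %% h) + 1L
    cj <- ((pick - 1L) %/% h) + 1L
    jitter <- runif(2L, -0.45, 0.45)
    cand <- c(ci + jitter[1L], cj + jitter[2L])
    if (nrow(centers) == 0L ||
        all((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2 >=
            (radii + radius + 2)^2)) {
      return(cand)
    }
  }
  stop("cannot place ", what, ": the ", zone_name,
       " is too small for the requested feature count/spacing")
}

erode_box <- function(mask, margin) {
  # cheap erosion by a square margin, adequate for keeping features inside
  m <- as.integer(ceiling(margin))
  if (m <= 0L) return(mask)
  k <- matrix(1, 2L * m + 1L, 2L * m + 1L)
  matrix(EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1), k)) > 0.5,
         nrow(mask), ncol(mask))
}

#' Generate one synthetic facial-skin sample
#'
#' Renders a smooth skin-like background and stamps in dark curvilinear
#' wrinkle strokes (inside the wrinkle zone), dark round pore pits (inside
#' the pore zone, placed without overlap) and pore-like distractors strictly
#' outside both zones. Each feature has a Gaussian cross-section; its fine
#' mask marks the pixels where the intensity drop exceeds half the feature's
#' contrast. Coarse annotations are disk dilations of the fine masks,
#' emulating over-thick manual labeling.
#'
#' @param spec A [scene_spec()].
#' @param zones A [zone_layout()]; defaults to [default_zone_layout()] of the
#'   spec's size.
#' @param annotation_radius Disk radius (pixels) of the coarse-annotation
#'   dilation.
#' @return An object of class `synthetic_sample` with fields `image`
#'   (\[H, W, 3\] array in \[0, 1\]), `fine_wrinkle_mask`, `fine_pore_mask`,
#'   `coarse_wrinkle_annotation`, `coarse_pore_annotation` (logical matrices),
#'   `zones` and `spec`.
#' @export
generate_scene <- function(spec, zones = default_zone_layout(spec$height, spec$width),
                           annotation_radius = 3) {
  validate_scene_spec(spec)
  if (!identical(dim(zones$wrinkle_zone), c(spec$height, spec$width))) {
    stop("zone masks must match the scene size")
  }
  h <- spec$height; w <- spec$width
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  # background: low-passed white noise around background_mean + lighting ramp
  bg <- matrix(rnorm(h * w), h, w)
  bg <- gaussian_blur(bg, spec$background_smoothness)
  bg <- bg / max(sd(bg), 1e-12) * spec$noise_amplitude + spec$background_mean
  if (spec$lighting_gradient != 0) {
    ramp <- matrix(rep(seq(-0.5, 0.5, length.out = w), each = h), h, w)
    bg <- bg + spec$lighting_gradient * ramp
  }

  drop <- matrix(0, h, w)
  wr_sup <- matrix(FALSE, h, w)
  po_sup <- matrix(FALSE, h, w)

  # wrinkles: splines inside the wrinkle zone (rejection sampling keeps every
  # fine-mask pixel inside the zone)
  if (spec$n_wrinkles > 0L) {
    margin <- spec$wrinkle_thickness_range[2L] / 2 + 2
    core <- erode_box(zones$wrinkle_zone, margin)
    if (!any(core)) {
      stop("cannot place wrinkle stroke: the wrinkle zone is too small ",
           "for the requested thickness")
    }
    core_idx <- which(core)
    extent <- 0.35 * min(h, w)
    for (k in seq_len(spec$n_wrinkles)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        pick <- core_idx[sample.int(length(core_idx), 1L)]
        ci <- ((pick - 1L) %% h) + 1L
        cj <- ((pick - 1L) %/% h) + 1L
        curve <- sample_stroke(ci, cj, extent)
        thick <- runif(1L, spec$wrinkle_thickness_range[1L],
                       spec$wrinkle_thickness_range[2L])
        # keep the whole support inside the zone: test curve points + margin
        ok <- all(curve[, 1L] > 1, curve[, 1L] < h,
                  curve[, 2L] > 1, curve[, 2L] < w)
        if (ok) {
          ii <- pmin(pmax(round(curve[, 1L]), 1L), h)
          jj <- pmin(pmax(round(curve[, 2L]), 1L), w)
          ok <- all(core[cbind(ii, jj)])
        }
        if (!ok) next
        st <- stamp_stroke(drop, wr_sup, curve, thick, spec$wrinkle_contrast, h, w)
        # strict containment check of the realized support
        new_sup <- st$support & !wr_sup
        if (any(new_sup & !zones$wrinkle_zone)) next
        drop <- st$drop; wr_sup <- st$support
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("cannot place wrinkle stroke: the wrinkle zone is too small ",
             "for stroke ", k)
      }
    }
  }

  # pores: non-overlapping Gaussian pits inside the pore zone
  if (spec$n_pores > 0L) {
    rmax <- spec$pore_radius_range[2L]
    core <- erode_box(zones$pore_zone, rmax + 1)
    if (!any(core)) {
      stop("cannot place pore: the pore zone is too small for the requested radius")
    }
    core_idx <- which(core)
    centers <- matrix(numeric(0), 0L, 2L)
    radii <- numeric(0)
    for (k in seq_len(spec$n_pores)) {
      r <- runif(1L, spec$pore_radius_range[1L], spec$pore_radius_range[2L])
      cand <- place_center(core_idx, h, centers, radii, r, "pore", "pore zone")
      centers <- rbind(centers, cand)
      radii <- c(radii, r)
      st <- stamp_pore(drop, po_sup, cand[1L], cand[2L], r, spec$pore_contrast)
      drop <- st$drop; po_sup <- st$support
    }
  }

  # distractors: pore-like pits strictly outside both zones (and all masks)
  if (spec$n_distractors > 0L) {
    rmax <- spec$pore_radius_range[2L]
    outside <- !(zones$wrinkle_zone | zones$pore_zone)
    # keep distractor support + a safety ring away from the zones
    forbidden <- matrix(EBImage::imageData(EBImage::dilate(
      EBImage::Image((zones$wrinkle_zone | zones$pore_zone) * 1),
      matrix(1, 2L * ceiling(rmax + 3) + 1L, 2L * ceiling(rmax + 3) + 1L))) > 0.5,
      h, w)
    allowed <- outside & !forbidden & !border_band(h, w, ceiling(rmax + 2))
    if (!any(allowed)) {
      stop("cannot place distractor: no room outside the wrinkle/pore zones")
    }
    allowed_idx <- which(allowed)
    centers <- matrix(numeric(0), 0L, 2L)
    radii <- numeric(0)
    dd <- matrix(FALSE, h, w) # distractor support, kept out of all masks
    for (k in seq_len(spec$n_distractors)) {
      r <- runif(1L, spec$pore_radius_range[1L], spec$pore_radius_range[2L])
      cand <- place_center(allowed_idx, h, centers, radii, r,
                           "distractor", "area outside the zones")
      centers <- rbind(centers, cand)
      radii <- c(radii, r)
      st <- stamp_pore(drop, dd, cand[1L], cand[2L], r, spec$pore_contrast)
      drop <- st$drop
    }
  }

  gray <- clip01(bg - drop)
  image <- array(0, c(h, w, 3L))
  image[, , 1L] <- clip01(gray * 1.06)
  image[, , 2L] <- gray
  image[, , 3L] <- clip01(gray * 0.88)

  sample_obj <- structure(list(
    image = image,
    fine_wrinkle_mask = wr_sup,
    fine_pore_mask = po_sup,
    coarse_wrinkle_annotation = make_coarse_annotation(wr_sup, annotation_radius),
    coarse_pore_annotation = make_coarse_annotation(po_sup, annotation_radius),
    zones = zones,
    spec = spec
  ), class = "synthetic_sample")
  sample_obj
}

border_band <- function(h, w, m) {
  b <- matrix(FALSE, h, w)
  m <- as.integer(m)
  if (m > 0L) {
    b[c(seq_len(m), (h - m + 1L):h), ] <- TRUE
    b[, c(seq_len(m), (w - m + 1L):w)] <- TRUE
  }
  b
}

#' Thicken a fine mask into a coarse manual-style annotation
#'
#' Morphological dilation with a disk of the given radius, emulating manual
#' labeling performed with a thickness that generously covers the feature.
#' The output always contains the input.
#'
#' @param fine_mask Logical (or 0/1) matrix.
#' @param dilation_radius Disk radius in pixels (>= 0); radius 0 returns the
#'   input unchanged.
#' @return Logical matrix.
#' @export
make_coarse_annotation <- function(fine_mask, dilation_radius = 3) {
  if (!is.numeric(dilation_radius) || length(dilation_radius) != 1L ||
      dilation_radius < 0) {
    stop("dilation_radius must be a single number >= 0")
  }
  m <- fine_mask != 0
  if (dilation_radius == 0 || !any(m)) {
    return(m)
  }
  k <- disk_kernel(dilation_radius)
  matrix(EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), k)) > 0.5,
         nrow(m), ncol(m))
}

#' Generate a reproducible sequence of synthetic samples
#'
#' Per-sample seeds are derived arithmetically from `(seed, index)`, so the
#' full dataset is a pure function of its arguments.
#'
#' @param spec_template A [scene_spec()] whose seed field is ignored.
#' @param n Number of samples (>= 1).
#' @param seed Integer master seed.
#' @param zones Optional [zone_layout()] shared by all samples.
#' @param annotation_radius Coarse-annotation dilation radius.
#' @return List of `synthetic_sample` objects.
#' @export
generate_dataset <- function(spec_template, n, seed,
                             zones = default_zone_layout(spec_template$height,
                                                         spec_template$width),
                             annotation_radius = 3) {
  validate_scene_spec(spec_template)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single integer >= 1")
  }
  n <- as.integer(n)
  lapply(seq_len(n), function(i) {
    s <- spec_template
    s$seed <- derive_seed(seed, i)
    generate_scene(s, zones = zones, annotation_radius = annotation_radius)
  })
}

#' Derive a per-item seed from a master seed and an index
#'
#' @param seed Integer master seed.
#' @param index 1-based item index.
#' @return Integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, index) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + 7919 * index) %% 2147483646 + 1)
}

#' Deterministic train/validation index split
#'
#' @param n Total number of samples.
#' @param n_train Number of training samples (< n).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `val`, disjoint and jointly
#'   covering `1:n`.
#' @export
split_dataset <- function(n, n_train, seed) {
  if (n_train >= n || n_train < 1) stop("n_train must lie in [1, n - 1]")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(seed, 999983L))
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(n_train)]), val = sort(idx[(n_train + 1L):n]))
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf(
    "<synthetic_sample %dx%d: %d wrinkle px, %d pore px, seed %d>\n",
    nrow(x$fine_wrinkle_mask), ncol(x$fine_wrinkle_mask),
    sum(x$fine_wrinkle_mask), sum(x$fine_pore_mask), x$spec$seed))
  invisible(x)
}
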