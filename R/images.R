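#' Read an image into the [0, 1] intensity convention
#'
#' Reads PNG or TIFF images. 8-bit values are scaled by 255 and 16-bit values
#' by 65535, so all downstream filters operate on intensities in \[0, 1\].
#' Grayscale files yield a matrix, color files an \[H, W, 3\] array (an alpha
#' channel, if present, is dropped).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (grayscale) or \[H, W, 3\] array with values in
#'   \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG and TIFF are supported)")
  )
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) {
    img <- img[, , 1L]
  }
  img
}

#' Write an intensity image as 8-bit PNG
#'
#' @param image Matrix or \[H, W, 3\] array with values in \[0, 1\]; values are
#'   clipped to that range before quantization.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Write a binary mask as a 0/255 single-channel PNG
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  png::writePNG(m, target = path)
  invisible(path)
}

#' Read a 0/255 mask PNG back as a logical matrix
#'
#' @param path Path to a mask PNG.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' Convert a color image to grayscale
#'
#' Luma-weighted combination with the ITU-R BT.601 weights
#' (0.299, 0.587, 0.114).
#'
#' @param image \[H, W, 3\] array with values in \[0, 1\].
#' @return Numeric matrix in \[0, 1\].
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("to_grayscale() expects a 3-channel [H, W, 3] image array")
  }
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Gaussian blur with reflective (symmetric) borders
#'
#' Separable Gaussian filtering. The kernel is truncated at
#' `ceiling(3.5 * sigma)` taps per side and renormalized; borders are handled
#' by half-sample symmetric reflection, so a constant image is exactly
#' invariant.
#'
#' @param x Numeric matrix.
#' @param sigma Standard deviation in pixels (> 0).
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  cpp_sepconv_reflect(as.matrix(x), gaussian_kernel_1d(sigma))
}

#' One-dimensional Gaussian kernel used by [gaussian_blur()]
#'
#' @param sigma Standard deviation in pixels.
#' @return Normalized numeric vector of odd length.
#' @export
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# disk structuring element: pixels with x^2 + y^2 <= r^2 (radius 1 -> plus)
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= radius^2
  matrix(as.numeric(k), 2L * r + 1L, 2L * r + 1L)
}
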