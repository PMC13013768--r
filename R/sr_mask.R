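# Specular-reflection (SR) masks: extraction by luma thresholding, Gaussian
# refinement into soft masks, rigid transforms, and morphological dilation.
# This is the shared core of both SR augmentation routes (generation and
# inpainting).

#' Convert an RGB image to grayscale luma
#'
#' Uses ITU-R BT.601 luma, Y = 0.299 R + 0.587 G + 0.114 B, rounded to the
#' nearest integer — the default of mainstream imaging libraries.
#'
#' @param img An H x W x 3 image array.
#' @return An H x W integer matrix in 0..255.
#' @export
to_grayscale <- function(img) {
  validate_image(img)
  y <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  dim(y) <- dim(img)[1:2]   # guard against dimension dropping for H = 1
  storage.mode(y) <- "integer"
  y
}

#' Extract a specular-reflection mask by thresholding
#'
#' A pixel belongs to the SR mask when its grayscale luma is strictly
#' greater than `threshold` (default 245): specular highlights are
#' near-saturated, far above mucosal tissue intensities.
#'
#' @param img An H x W x 3 image array.
#' @param threshold Luma threshold in 0..255; strictly-greater comparison.
#' @return An H x W logical matrix, `TRUE` at SR pixels.
#' @export
extract_sr_mask <- function(img, threshold = 245L) {
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  to_grayscale(img) > threshold
}

# sigma implied by a Gaussian kernel of full width k (the usual
# size -> sigma rule of mainstream imaging libraries).
sigma_from_ksize <- function(k) 0.3 * ((k - 1) / 2 - 1) + 0.8

#' Refine a binary SR mask into soft highlight and halo masks
#'
#' Blurs the 0/1 mask with two Gaussian filters: a small fixed-size kernel
#' (`k1`, default 5) giving the smooth highlight core, and a wider kernel
#' auto-sized from `sigma2` giving the localized colour-spreading halo
#' around the highlight. Following the common imaging-library convention, a
#' kernel size of 0 means "derive the size from sigma", which is how the
#' halo kernel is specified; its width is the nearest odd integer
#' >= 6*sigma2 + 1. Borders are handled by symmetric reflection.
#'
#' @param mask An H x W logical matrix.
#' @param k1 Odd kernel width of the highlight filter; its sigma follows the
#'   standard size-to-sigma rule 0.3*((k-1)/2 - 1) + 0.8.
#' @param sigma2 Sigma of the halo filter (kernel auto-sized).
#' @return A list with numeric H x W matrices `highlight` and `halo`, both
#'   in \[0, 1\].
#' @export
refine_mask <- function(mask, k1 = 5L, sigma2 = 3.0) {
  validate_mask(mask)
  if (k1 < 1L || k1 %% 2L != 1L) stop("k1 must be an odd positive integer")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  m <- mask * 1
  highlight <- gaussian_blur_matrix(m, sigma_from_ksize(k1), k1)
  halo <- gaussian_blur_matrix(m, sigma2, 0L)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  list(highlight = clamp01(highlight), halo = clamp01(halo))
}

#' Dilate a binary mask with a rectangular structuring element
#'
#' Morphological binary dilation with an all-true `kernel_h` x `kernel_w`
#' rectangle anchored at its centre; for even sizes the anchor is at
#' (floor(h/2), floor(w/2)), matching the usual library convention.
#' Pixels outside the image are treated as background.
#'
#' @param mask An H x W logical matrix.
#' @param kernel_h,kernel_w Structuring element size in pixels (default
#'   10 x 10).
#' @return A dilated H x W logical matrix; never has fewer `TRUE` pixels
#'   than the input.
#' @export
dilate_mask <- function(mask, kernel_h = 10L, kernel_w = 10L) {
  validate_mask(mask)
  if (kernel_h < 1L || kernel_w < 1L) stop("kernel sizes must be >= 1")
  h <- nrow(mask); w <- ncol(mask)
  ay <- kernel_h %/% 2L; ax <- kernel_w %/% 2L
  out <- matrix(FALSE, h, w)
  for (dy in (0:(kernel_h - 1L)) - ay) {
    r_lo <- max(1L, 1L - dy); r_hi <- min(h, h - dy)
    if (r_lo > r_hi) next
    rows_src <- r_lo:r_hi
    rows_dst <- rows_src + dy
    for (dx in (0:(kernel_w - 1L)) - ax) {
      c_lo <- max(1L, 1L - dx); c_hi <- min(w, w - dx)
      if (c_lo > c_hi) next
      cols_src <- c_lo:c_hi
      out[rows_dst, cols_src + dx] <- out[rows_dst, cols_src + dx] | mask[rows_src, cols_src]
    }
  }
  out
}

# Rigid transform of a numeric matrix or logical mask: rotation by a
# multiple of 90 degrees counter-clockwise, then optional horizontal
# (left-right) and vertical (top-bottom) flips.
transform_matrix <- function(m, rotation = 0L, flip_h = FALSE, flip_v = FALSE) {
  rotation <- as.integer(rotation) %% 360L
  if (!rotation %in% c(0L, 90L, 180L, 270L))
    stop("rotation must be one of 0, 90, 180, 270 degrees")
  rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE] # 90 degrees CCW
  for (i in seq_len(rotation %/% 90L)) m <- rot90(m)
  if (flip_h) m <- m[, ncol(m):1, drop = FALSE]
  if (flip_v) m <- m[nrow(m):1, , drop = FALSE]
  m
}

#' Rigidly transform a binary mask
#'
#' Rotates the mask by a multiple of 90 degrees (counter-clockwise) and then
#' applies optional horizontal/vertical flips. The transform is exact on the
#' pixel grid, so the number of `TRUE` pixels is conserved. For 90/270
#' degree rotations of non-square masks, the output dimensions swap.
#'
#' @param mask An H x W logical matrix.
#' @param rotation One of 0, 90, 180, 270 (degrees).
#' @param flip_h,flip_v Apply a horizontal / vertical flip after rotation.
#' @return The transformed logical matrix.
#' @export
transform_mask <- function(mask, rotation = 0L, flip_h = FALSE, flip_v = FALSE) {
  validate_mask(mask)
  transform_matrix(mask, rotation, flip_h, flip_v)
}

#' Fraction of mask pixels that are set
#'
#' A simple QC statistic used to reject degenerate SR donors.
#'
#' @param mask An H x W logical matrix.
#' @return A real in \[0, 1\]: `TRUE` pixels over total pixels.
#' @export
mask_area_fraction <- function(mask) {
  validate_mask(mask)
  mean(mask)
}

#' Remove small connected components from a mask
#'
#' Optional QC filter (off by default throughout the pipeline): drops
#' 4-connected components with fewer than `min_area` pixels. The default
#' pipeline deliberately applies no morphological shape/area filtering to
#' extracted SR masks.
#'
#' @param mask An H x W logical matrix.
#' @param min_area Minimum component area in pixels to keep.
#' @return A filtered logical matrix.
#' @export
filter_mask_area <- function(mask, min_area = 0L) {
  validate_mask(mask)
  if (min_area <= 1L) return(mask)
  lab <- EBImage::bwlabel(t(mask) * 1)
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_area)
  t(matrix(as.integer(lab) %in% keep, nrow(lab), ncol(lab)))
}
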