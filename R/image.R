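#' @importFrom stats runif rnorm
NULL

# Images are plain H x W x 3 integer arrays with values in 0..255, channel
# order RGB. Masks are H x W logical matrices. Keeping base arrays (rather
# than a wrapper class) makes every operation transparent to inspect and
# trivially composable with base R.

validate_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(what, " has zero spatial extent")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(what, " intensities must lie in [0, 255]")
  invisible(img)
}

validate_mask <- function(mask, img = NULL, what = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(what, " must be an H x W logical matrix")
  if (!is.null(img) && !identical(dim(mask), dim(img)[1:2]))
    stop(what, " dimensions do not match the image")
  invisible(mask)
}

# Round and clamp a numeric array into the 8-bit integer range.
clip8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Construct a constant image
#'
#' @param height,width Spatial dimensions in pixels.
#' @param value Fill intensity, either a scalar or an RGB triple.
#' @return An H x W x 3 integer array.
#' @export
blank_image <- function(height, width, value = 0L) {
  value <- rep(as.integer(value), length.out = 3L)
  img <- array(0L, c(height, width, 3L))
  for (ch in 1:3) img[, , ch] <- value[ch]
  img
}

#' Read an image file
#'
#' Reads a PNG or JPEG file into the package's canonical representation:
#' an H x W x 3 integer array in 0..255, channel order RGB. Grayscale files
#' are replicated to three channels; an alpha channel is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An H x W x 3 integer array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else {
      e <- EBImage::readImage(path)
      a <- as.array(e)
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    }
  }, error = function(err) stop("cannot decode image ", path, ": ", conditionMessage(err)))
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[1] < 1L || dim(arr)[2] < 1L) stop("zero-size image: ", path)
  nc <- dim(arr)[3]
  if (nc == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  if (nc == 2L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE] # gray + alpha
  if (nc >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  clip8(arr * 255)
}

#' Write an image file
#'
#' PNG output is lossless: reading the file back yields a bit-identical
#' array. JPEG is supported for export only and is lossy.
#'
#' @param img An H x W x 3 integer array in 0..255.
#' @param path Destination path; format chosen by extension (.png or .jpg).
#' @param quality JPEG quality in (0, 100]; ignored for PNG.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, quality = 95) {
  validate_image(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    e <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
    EBImage::writeImage(e, path, quality = quality)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Read and write binary masks as PNG
#'
#' Masks are stored as single-channel 0/255 PNG files.
#'
#' @param mask An H x W logical matrix.
#' @param path PNG path.
#' @return `read_mask` returns a logical matrix; `write_mask` returns `path`.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr > 0.5
}

# --- low-level raster helpers ------------------------------------------------

# Reflect arbitrary (possibly out-of-range) 1-based indices into 1..n using
# symmetric (edge-including) reflection: for n = 4, indices ... 2 1 | 1 2 3 4 | 4 3 ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Separable Gaussian convolution of a numeric matrix with symmetric border
# padding. `ksize` is the full (odd) kernel width; 0 or NULL derives it from
# sigma as the nearest odd integer >= 6*sigma + 1.
gaussian_blur_matrix <- function(mat, sigma, ksize = NULL) {
  stopifnot(sigma > 0)
  if (is.null(ksize) || ksize == 0L) {
    ksize <- ceiling(6 * sigma + 1)
    if (ksize %% 2L == 0L) ksize <- ksize + 1L
  }
  if (ksize %% 2L != 1L) stop("kernel size must be odd")
  half <- (ksize - 1L) %/% 2L
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- w / sum(w)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    idx <- reflect_index((1L - half):(n + half), n)
    out <- 0
    if (along_rows) {
      padded <- m[idx, , drop = FALSE]
      for (j in seq_len(ksize)) out <- out + w[j] * padded[j:(j + n - 1L), , drop = FALSE]
    } else {
      padded <- m[, idx, drop = FALSE]
      for (j in seq_len(ksize)) out <- out + w[j] * padded[, j:(j + n - 1L), drop = FALSE]
    }
    out
  }
  conv1(conv1(mat, TRUE), FALSE)
}

# Bilinear resize of a numeric matrix to out_h x out_w (EBImage backend).
resize_matrix <- function(mat, out_h, out_w, bilinear = TRUE) {
  e <- EBImage::Image(t(mat))
  r <- EBImage::resize(e, w = out_w, h = out_h,
                       filter = if (bilinear) "bilinear" else "none")
  t(as.array(r))
}

# Bilinear resize of an image array; returns 8-bit integers.
resize_image <- function(img, out_h, out_w) {
  e <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(e, w = out_w, h = out_h, filter = "bilinear")
  clip8(aperm(as.array(r), c(2, 1, 3)) * 255)
}
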