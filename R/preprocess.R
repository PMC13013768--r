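#' Preprocessing configuration
#'
#' @param target_size Output side length in pixels, 150 or 224 — the two
#'   input resolutions used for model training.
#' @param pad_value Border intensity used when padding to a square
#'   (default 0; endoscopy backgrounds are dark).
#' @param alpha Coordination-noise amplitude: the crop centre is shifted by
#'   independent draws from Uniform(-alpha, alpha) times the box width and
#'   height. 0 disables the jitter.
#' @return A `specaug_preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 224L, pad_value = 0L, alpha = 0.1) {
  target_size <- as.integer(target_size)
  if (!target_size %in% c(150L, 224L)) stop("target_size must be 150 or 224")
  if (alpha < 0) stop("alpha must be >= 0")
  if (pad_value < 0 || pad_value > 255) stop("pad_value must be in [0, 255]")
  structure(list(target_size = target_size, pad_value = as.integer(pad_value),
                 alpha = alpha),
            class = "specaug_preprocess_config")
}

#' Pad an image to a square
#'
#' Adds a constant border on all four sides so the output is S x S with
#' S = max(height, width), keeping the content centred. When the total
#' padding is odd, the extra pixel goes toward the bottom/right. Content
#' pixels are never altered, so the aspect ratio of the content is exact.
#'
#' @param img An H x W x 3 image array.
#' @param pad_value Border intensity in 0..255.
#' @return An S x S x 3 image array.
#' @export
pad_to_square <- function(img, pad_value = 0L) {
  validate_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- max(h, w)
  if (h == s && w == s) return(img)
  top <- (s - h) %/% 2L
  left <- (s - w) %/% 2L
  out <- blank_image(s, s, pad_value)
  out[top + seq_len(h), left + seq_len(w), ] <- img
  out
}

#' Crop a bounding box with coordination noise
#'
#' Draws independent offsets dx, dy ~ Uniform(-alpha, alpha), shifts the
#' annotated box by (round(dx * width), round(dy * height)) pixels, clamps
#' the shifted box back inside the image, and returns the crop. The output
#' always has the box's own height x width; with `alpha = 0` the crop equals
#' the annotated box contents exactly.
#'
#' @param img An H x W x 3 image array.
#' @param bbox A [bounding_box()] valid for `img`.
#' @param alpha Noise amplitude (fraction of the box side).
#' @param rng A [seeded_rng()] stream.
#' @return A `bbox$height` x `bbox$width` x 3 image array.
#' @export
crop_with_coordination_noise <- function(img, bbox, alpha, rng) {
  validate_image(img)
  validate_bbox_in_image(bbox, img)
  h <- dim(img)[1]; w <- dim(img)[2]
  d <- rng_unif(rng, 2L, -alpha, alpha)
  x0 <- bbox$x_min + as.integer(round(d[1] * bbox$width))
  y0 <- bbox$y_min + as.integer(round(d[2] * bbox$height))
  x0 <- min(max(x0, 0L), w - bbox$width)
  y0 <- min(max(y0, 0L), h - bbox$height)
  img[y0 + seq_len(bbox$height), x0 + seq_len(bbox$width), , drop = FALSE]
}

#' Preprocess one annotated sample
#'
#' Composition crop -> pad-to-square -> bilinear resize: the polyp box
#' (jittered by coordination noise) is cropped, padded to a square so the
#' resize cannot distort the polyp's aspect ratio, and scaled to
#' `cfg$target_size`.
#'
#' @param img An H x W x 3 image array.
#' @param bbox The polyp [bounding_box()].
#' @param cfg A [preprocess_config()].
#' @param rng A [seeded_rng()] stream (used only when `cfg$alpha > 0`).
#' @return A `target_size` x `target_size` x 3 image array.
#' @export
preprocess_sample <- function(img, bbox, cfg = preprocess_config(), rng = seeded_rng(0)) {
  crop <- crop_with_coordination_noise(img, bbox, cfg$alpha, rng)
  sq <- pad_to_square(crop, cfg$pad_value)
  resize_image(sq, cfg$target_size, cfg$target_size)
}
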