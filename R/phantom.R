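# Seeded endoscopy-phantom generator. Phantoms are structural stand-ins for
# narrow-band-imaging polyp stills: a dark reddish mucosal background with a
# centre-lit falloff, one brighter elliptical "polyp" carrying a sinusoidal
# surface texture whose spatial frequency encodes the class (AD fine, HP
# coarse), additive sensor noise, and saturated elliptical specular blobs
# with an exactly known ground-truth mask. Tissue intensities are clamped
# below the SR threshold so the planted mask is recoverable pixel-for-pixel.

#' Phantom generator configuration
#'
#' @param n_images Number of phantoms in the set.
#' @param image_size Square image side in pixels.
#' @param class_balance Fraction of images labelled AD; realized counts are
#'   `floor(n * balance)` AD and the remainder HP.
#' @param sr_blob_count_range Inclusive integer range of specular blobs per
#'   image.
#' @param sr_blob_radius_range Blob semi-axis range in pixels.
#' @param sr_intensity_range Blob intensity range; the low end must stay
#'   >= 246 for the blobs to be detectable at the standard threshold of 245.
#' @param background_mean Mean background intensity (green channel); red and
#'   blue are offset to give the reddish cast of mucosa.
#' @param polyp_contrast Added intensity of the polyp over background.
#' @param texture_freq_ad,texture_freq_hp Sinusoidal surface-texture
#'   frequency (cycles per image side) for each class; AD textures are
#'   finer, emulating the denser surface patterns of adenomas.
#' @param texture_amplitude Texture amplitude in intensity units.
#' @param noise_sigma Additive Gaussian sensor noise sigma.
#' @param seed Base seed; each phantom derives its own stream from
#'   `(seed, idx)`, so any single phantom is reproducible in isolation.
#' @return A `specaug_phantom_config` list.
#' @export
phantom_config <- function(n_images = 100L, image_size = 224L, class_balance = 0.5,
                           sr_blob_count_range = c(1L, 6L),
                           sr_blob_radius_range = c(2, 10),
                           sr_intensity_range = c(246L, 255L),
                           background_mean = 90, polyp_contrast = 40,
                           texture_freq_ad = 18, texture_freq_hp = 6,
                           texture_amplitude = 15, noise_sigma = 4, seed = 0L) {
  if (n_images < 1L) stop("n_images must be >= 1")
  if (class_balance <= 0 || class_balance >= 1) stop("class_balance must be in (0, 1)")
  if (sr_intensity_range[1] < 246)
    warning("sr_intensity_range low end < 246: planted blobs may be missed at threshold 245")
  if (background_mean + polyp_contrast + texture_amplitude + 3 * noise_sigma >= 246)
    warning("tissue intensities may cross the SR threshold; ",
            "false-positive SR pixels are prevented only by the 245 clamp")
  structure(list(n_images = as.integer(n_images), image_size = as.integer(image_size),
                 class_balance = class_balance,
                 sr_blob_count_range = as.integer(sr_blob_count_range),
                 sr_blob_radius_range = sr_blob_radius_range,
                 sr_intensity_range = as.integer(sr_intensity_range),
                 background_mean = background_mean, polyp_contrast = polyp_contrast,
                 texture_freq_ad = texture_freq_ad, texture_freq_hp = texture_freq_hp,
                 texture_amplitude = texture_amplitude, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "specaug_phantom_config")
}

phantom_seed <- function(cfg, idx) {
  as.integer((as.double(cfg$seed) * 7919 + as.double(idx) * 104729) %% 2147483629)
}

phantom_label <- function(cfg, idx) {
  n_ad <- floor(cfg$n_images * cfg$class_balance)
  if (idx <= n_ad) "AD" else "HP"
}

# Filled-ellipse pixel set: centre (cy, cx), semi-axes (ry, rx), rotated by
# theta radians.
ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  ys <- matrix(seq_len(h), h, w) - cy
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * xs + sin(theta) * ys
  v <- -sin(theta) * xs + cos(theta) * ys
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate one phantom image
#'
#' @param cfg A [phantom_config()].
#' @param idx Image index in `1..cfg$n_images`; determines the class label
#'   (the first `floor(n * balance)` indices are AD) and, together with
#'   `cfg$seed`, the phantom's private random stream.
#' @param rng Optional explicit [seeded_rng()] stream; by default one is
#'   derived deterministically from `(cfg$seed, idx)`.
#' @return A list: `image` (H x W x 3 array), `label`, `bbox` (tight polyp
#'   [bounding_box()]), and `mask` (the exact planted SR mask).
#' @export
generate_phantom <- function(cfg, idx, rng = seeded_rng(phantom_seed(cfg, idx))) {
  s <- cfg$image_size
  label <- phantom_label(cfg, idx)

  # centre-lit radial falloff over a reddish base
  ys <- matrix(seq_len(s), s, s); xs <- t(ys)
  r2 <- ((ys - (s + 1) / 2)^2 + (xs - (s + 1) / 2)^2) / ((s / 2)^2)
  vign <- 1 - 0.25 * pmin(r2, 1)
  base <- c(cfg$background_mean + 25, cfg$background_mean, cfg$background_mean - 25)

  # polyp ellipse + class-dependent surface texture
  pc <- rng_unif(rng, 2L, 0.32 * s, 0.68 * s)
  ax <- rng_unif(rng, 2L, s / 8, s / 5)
  pth <- rng_unif(rng, 1L, 0, pi)
  polyp <- ellipse_mask(s, s, pc[1], pc[2], ax[1], ax[2], pth)
  # soft rim: taper the polyp elevation over the outer 20% of its radius so
  # the lesion boundary is a gradual mucosal slope, not a step edge
  u0 <- cos(pth) * (xs - pc[2]) + sin(pth) * (ys - pc[1])
  v0 <- -sin(pth) * (xs - pc[2]) + cos(pth) * (ys - pc[1])
  rad <- sqrt((u0 / ax[2])^2 + (v0 / ax[1])^2)
  pw <- pmin(1, pmax(0, (1.1 - rad) / 0.2))
  freq <- if (label == "AD") cfg$texture_freq_ad else cfg$texture_freq_hp
  tth <- rng_unif(rng, 1L, 0, pi)
  tph <- rng_unif(rng, 1L, 0, 2 * pi)
  u <- cos(tth) * xs + sin(tth) * ys
  texture <- cfg$texture_amplitude * sin(2 * pi * freq * u / s + tph)

  img <- array(0, c(s, s, 3L))
  for (ch in 1:3) {
    plane <- base[ch] * vign + pw * (cfg$polyp_contrast + texture)
    plane <- plane + rng_norm(rng, s * s, cfg$noise_sigma)
    # sensor clamp just below the SR threshold: tissue never reads as SR
    img[, , ch] <- pmin(pmax(plane, 0), 245)
  }

  # saturated specular blobs inside / near the polyp
  n_blobs <- rng_int(rng, 1L, cfg$sr_blob_count_range[1], cfg$sr_blob_count_range[2])
  mask <- matrix(FALSE, s, s)
  if (n_blobs > 0L) {
    for (b in seq_len(n_blobs)) {
      bc_y <- min(max(pc[1] + rng_unif(rng, 1L, -1.3 * ax[1], 1.3 * ax[1]), 2), s - 1)
      bc_x <- min(max(pc[2] + rng_unif(rng, 1L, -1.3 * ax[2], 1.3 * ax[2]), 2), s - 1)
      br <- rng_unif(rng, 2L, cfg$sr_blob_radius_range[1], cfg$sr_blob_radius_range[2])
      bth <- rng_unif(rng, 1L, 0, pi)
      intensity <- rng_int(rng, 1L, cfg$sr_intensity_range[1], cfg$sr_intensity_range[2])
      blob <- ellipse_mask(s, s, bc_y, bc_x, br[1], br[2], bth)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[blob] <- intensity
        img[, , ch] <- plane
      }
      mask <- mask | blob
    }
  }

  rows <- which(rowSums(polyp) > 0); cols <- which(colSums(polyp) > 0)
  bbox <- bounding_box(min(cols) - 1L, min(rows) - 1L,
                       max(cols) - min(cols) + 1L, max(rows) - min(rows) + 1L)
  list(image = clip8(img), label = label, bbox = bbox, mask = mask)
}

#' Generate a phantom dataset on disk
#'
#' Writes `cfg$n_images` phantom PNGs, their ground-truth SR mask PNGs, and
#' a `manifest.csv` under `out_dir`. Class counts follow the deterministic
#' floor-plus-remainder rule: `floor(n * class_balance)` AD, the rest HP.
#'
#' @param cfg A [phantom_config()].
#' @param out_dir Output directory.
#' @param verbose Log one line per phantom.
#' @return The dataset manifest.
#' @export
generate_phantom_set <- function(cfg, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", cfg$n_images)
  for (idx in seq_len(cfg$n_images)) {
    ph <- generate_phantom(cfg, idx)
    img_path <- file.path(out_dir, sprintf("phantom_%04d.png", idx))
    mask_path <- file.path(out_dir, sprintf("phantom_%04d_mask.png", idx))
    write_image(ph$image, img_path)
    write_mask(ph$mask, mask_path)
    if (verbose) message("phantom ", idx, ": ", ph$label, ", ",
                         sum(ph$mask), " SR px")
    rows[[idx]] <- data.frame(image_path = img_path, label = ph$label,
                              x_min = ph$bbox$x_min, y_min = ph$bbox$y_min,
                              width = ph$bbox$width, height = ph$bbox$height,
                              sr_mask_path = mask_path, stringsAsFactors = FALSE)
  }
  m <- validate_manifest(new_manifest(do.call(rbind, rows)))
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  invisible(m)
}
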