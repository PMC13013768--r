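# Baseline natural-image augmentations (rotation, flip, colour jitter,
# Gaussian noise, Gaussian blur) and the Fourier domain adaptation
# comparator. All operations preserve dimensions and the 8-bit range.

#' Base augmentation configuration
#'
#' @param enabled_ops Subset of `rotation`, `flip`, `color_jitter`,
#'   `gaussian_noise`, `gaussian_blur`.
#' @param rotation_max_deg Rotation angle drawn from
#'   Uniform(-max, +max) degrees.
#' @param jitter_strength Brightness/contrast/saturation each scaled by an
#'   independent factor from Uniform(1 - s, 1 + s).
#' @param noise_sigma Standard deviation of the additive Gaussian noise in
#'   intensity units.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param apply_prob Per-op application probability.
#' @return A `specaug_baseaug_config` list.
#' @export
base_aug_config <- function(enabled_ops = c("rotation", "flip", "color_jitter",
                                            "gaussian_noise", "gaussian_blur"),
                            rotation_max_deg = 30, jitter_strength = 0.2,
                            noise_sigma = 5, blur_sigma = 1.0, apply_prob = 0.5) {
  known <- c("rotation", "flip", "color_jitter", "gaussian_noise", "gaussian_blur")
  bad <- setdiff(enabled_ops, known)
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  if (apply_prob < 0 || apply_prob > 1) stop("apply_prob must be in [0, 1]")
  if (jitter_strength < 0 || jitter_strength > 1) stop("jitter_strength must be in [0, 1]")
  structure(list(enabled_ops = enabled_ops, rotation_max_deg = rotation_max_deg,
                 jitter_strength = jitter_strength, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma, apply_prob = apply_prob),
            class = "specaug_baseaug_config")
}

#' Rotate an image by an arbitrary angle
#'
#' Rotation about the image centre with bilinear interpolation; pixels whose
#' source falls outside the frame are filled by symmetric reflection of the
#' image, so no constant-colour wedges appear. Output dimensions equal
#' input dimensions.
#'
#' @param img An H x W x 3 image array.
#' @param angle_deg Rotation angle in degrees (counter-clockwise).
#' @return The rotated image array.
#' @export
rotate_image <- function(img, angle_deg) {
  validate_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- matrix(seq_len(h), h, w) - cy
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: sample the source at the backward-rotated coordinate
  sx <- cos(th) * xs + sin(th) * ys + cx
  sy <- -sin(th) * xs + cos(th) * ys + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ix0 <- reflect_index(as.integer(x0), w); ix1 <- reflect_index(as.integer(x0) + 1L, w)
  iy0 <- reflect_index(as.integer(y0), h); iy1 <- reflect_index(as.integer(y0) + 1L, h)
  out <- array(0, dim(img))
  for (ch in 1:3) {
    p <- img[, , ch]
    v <- (1 - fy) * ((1 - fx) * p[cbind(c(iy0), c(ix0))] + fx * p[cbind(c(iy0), c(ix1))]) +
      fy * ((1 - fx) * p[cbind(c(iy1), c(ix0))] + fx * p[cbind(c(iy1), c(ix1))])
    out[, , ch] <- matrix(v, h, w)
  }
  clip8(out)
}

#' Apply colour jitter
#'
#' Scales brightness, contrast and saturation by the given factors (in that
#' order), clipping to the 8-bit range after each step.
#'
#' @param img An H x W x 3 image array.
#' @param brightness,contrast,saturation Multiplicative factors.
#' @return The jittered image array.
#' @export
color_jitter <- function(img, brightness = 1, contrast = 1, saturation = 1) {
  validate_image(img)
  x <- img * brightness
  x <- pmin(pmax(x, 0), 255)
  mu <- mean(x)
  x <- (x - mu) * contrast + mu
  x <- pmin(pmax(x, 0), 255)
  gray <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  for (ch in 1:3) x[, , ch] <- gray + (x[, , ch] - gray) * saturation
  clip8(x)
}

#' Apply the baseline augmentation stack
#'
#' Each enabled op fires independently with probability `cfg$apply_prob`,
#' in the fixed order rotation, flip, colour jitter, Gaussian noise,
#' Gaussian blur. The flip axis (horizontal or vertical) is drawn uniformly
#' when the flip fires. Fully reproducible given the stream.
#'
#' @param img An H x W x 3 image array.
#' @param cfg A [base_aug_config()].
#' @param rng A [seeded_rng()] stream.
#' @return The augmented image array (same dimensions, 8-bit).
#' @export
apply_base_aug <- function(img, cfg = base_aug_config(), rng = seeded_rng(0)) {
  validate_image(img)
  on <- function(op) op %in% cfg$enabled_ops && rng_bern(rng, 1L, cfg$apply_prob)
  if (on("rotation")) {
    img <- rotate_image(img, rng_unif(rng, 1L, -cfg$rotation_max_deg, cfg$rotation_max_deg))
  }
  if (on("flip")) {
    if (rng_bern(rng, 1L)) img <- img[, dim(img)[2]:1, , drop = FALSE]
    else img <- img[dim(img)[1]:1, , , drop = FALSE]
  }
  if (on("color_jitter")) {
    f <- rng_unif(rng, 3L, 1 - cfg$jitter_strength, 1 + cfg$jitter_strength)
    img <- color_jitter(img, f[1], f[2], f[3])
  }
  if (on("gaussian_noise")) {
    img <- clip8(img + array(rng_norm(rng, length(img), cfg$noise_sigma), dim(img)))
  }
  if (on("gaussian_blur")) {
    out <- array(0, dim(img))
    for (ch in 1:3) out[, , ch] <- gaussian_blur_matrix(img[, , ch] * 1, cfg$blur_sigma)
    img <- clip8(out)
  }
  img
}

#' Fourier domain adaptation
#'
#' Replaces the low-frequency amplitude components of the source image with
#' those of the target while keeping the source phase everywhere: per
#' channel, both images are Fourier transformed, and inside the centred
#' square window of half-width `floor(beta * min(H, W))` around DC the
#' source amplitude is swapped for the target amplitude; the inverse
#' transform's real part is clipped to the 8-bit range. This transfers the
#' target's global illumination and colour tone onto the source's
#' structures. With `beta` small enough that the window is DC-only, the
#' output is the source shifted to the target's per-channel mean.
#'
#' @param source,target Image arrays of identical dimensions.
#' @param beta Window fraction in (0, 0.5].
#' @param quantize Round and clip the result to 8-bit integers (default).
#'   With `quantize = FALSE` the raw real-valued reconstruction is returned,
#'   which preserves the off-window amplitude spectrum and the source phase
#'   to floating-point precision.
#' @return The adapted image array.
#' @export
fda_transfer <- function(source, target, beta, quantize = TRUE) {
  validate_image(source); validate_image(target)
  if (!identical(dim(source), dim(target)))
    stop("source and target dimensions differ")
  if (beta <= 0 || beta > 0.5) stop("beta must be in (0, 0.5]")
  h <- dim(source)[1]; w <- dim(source)[2]
  b <- floor(beta * min(h, w))
  rows <- unique(((-b:b) %% h) + 1L)
  cols <- unique(((-b:b) %% w) + 1L)
  out <- array(0, dim(source))
  for (ch in 1:3) {
    fs <- stats::fft(source[, , ch] * 1)
    ft <- stats::fft(target[, , ch] * 1)
    amp <- Mod(fs)
    amp[rows, cols] <- Mod(ft)[rows, cols]
    phase <- Arg(fs)
    fnew <- amp * exp(1i * phase)
    out[, , ch] <- Re(stats::fft(fnew, inverse = TRUE)) / (h * w)
  }
  if (quantize) clip8(out) else out
}
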