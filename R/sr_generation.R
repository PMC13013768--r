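# SR generation: transplant a refined, rigidly transformed, colour-perturbed
# specular-highlight mask from a donor image onto a same-class target image.

no_donor_error <- function(msg) {
  stop(structure(class = c("specaug_no_donor", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' SR generation configuration
#'
#' @param threshold Luma threshold for donor mask extraction (strict `>`).
#' @param k1 Odd kernel width of the highlight Gaussian (see [refine_mask()]).
#' @param sigma2 Sigma of the halo Gaussian.
#' @param perturb_amplitude Half-width of the uniform integer RGB
#'   perturbation applied to the halo colour (simulates the colour blotches
#'   seen around real SR regions).
#' @param highlight_intensity Intensity painted at full highlight weight
#'   (default 255: saturated specular core).
#' @param min_mask_fraction Minimum donor mask area fraction; donors below
#'   it are considered degenerate.
#' @return A `specaug_srgen_config` list.
#' @export
sr_gen_config <- function(threshold = 245L, k1 = 5L, sigma2 = 3.0,
                          perturb_amplitude = 10L, highlight_intensity = 255L,
                          min_mask_fraction = 0.001) {
  if (perturb_amplitude < 0) stop("perturb_amplitude must be >= 0")
  if (min_mask_fraction <= 0 || min_mask_fraction >= 1)
    stop("min_mask_fraction must be in (0, 1)")
  structure(list(threshold = as.integer(threshold), k1 = as.integer(k1),
                 sigma2 = sigma2, perturb_amplitude = as.integer(perturb_amplitude),
                 highlight_intensity = as.integer(highlight_intensity),
                 min_mask_fraction = min_mask_fraction),
            class = "specaug_srgen_config")
}

#' Sample a same-class SR donor from a manifest
#'
#' Chooses uniformly at random among manifest samples that (a) carry the
#' requested class label, (b) have a non-degenerate SR mask at the
#' configured threshold, and (c) are not the target itself when another
#' candidate exists.
#'
#' @param m A manifest.
#' @param target_label Class label of the target image (`"AD"` or `"HP"`).
#' @param cfg A [sr_gen_config()].
#' @param rng A [seeded_rng()] stream.
#' @param exclude_path Optional image path of the target, excluded when
#'   more than one candidate exists.
#' @param eligibility Optional logical vector (one per manifest row) of
#'   precomputed donor eligibility, to avoid re-reading images in bulk runs.
#' @return The manifest row index of the sampled donor.
#' @export
sample_source <- function(m, target_label, cfg = sr_gen_config(), rng = seeded_rng(0),
                          exclude_path = NULL, eligibility = NULL) {
  validate_manifest(m)
  if (is.null(eligibility)) eligibility <- donor_eligibility(m, cfg)
  cand <- which(m$label == target_label & eligibility)
  if (length(cand) > 1L && !is.null(exclude_path))
    cand <- setdiff(cand, which(m$image_path == exclude_path))
  if (length(cand) == 0L)
    no_donor_error(sprintf("no SR donor with label %s and mask fraction >= %g",
                           target_label, cfg$min_mask_fraction))
  if (length(cand) == 1L) return(cand)
  rng_pick(rng, cand)
}

#' Precompute donor eligibility for every manifest row
#'
#' @param m A manifest.
#' @param cfg A [sr_gen_config()].
#' @return Logical vector: `TRUE` where the image's SR mask area fraction is
#'   at least `cfg$min_mask_fraction`.
#' @export
donor_eligibility <- function(m, cfg = sr_gen_config()) {
  vapply(m$image_path, function(p) {
    img <- read_image(p)
    mask_area_fraction(extract_sr_mask(img, cfg$threshold)) >= cfg$min_mask_fraction
  }, logical(1), USE.NAMES = FALSE)
}

#' Randomly perturb an RGB colour
#'
#' Offsets each channel independently by an integer drawn uniformly from
#' \{-delta, ..., +delta\}, then clips to 0..255.
#'
#' @param color Numeric RGB triple in 0..255.
#' @param delta Non-negative integer perturbation half-width.
#' @param rng A [seeded_rng()] stream.
#' @return An integer RGB triple.
#' @export
perturb_rgb <- function(color, delta, rng) {
  if (length(color) != 3L) stop("color must be an RGB triple")
  if (delta < 0) stop("delta must be >= 0")
  off <- if (delta == 0) c(0L, 0L, 0L) else rng_int(rng, 3L, -as.integer(delta), as.integer(delta))
  v <- round(color) + off
  as.integer(pmin(pmax(v, 0), 255))
}

#' Generate an SR-augmented image from a donor
#'
#' Pipeline: extract the donor's binary SR mask, refine it into soft
#' highlight and halo masks, apply one random rigid transform (rotation in
#' \{0, 90, 180, 270\} degrees; horizontal and vertical flips each with
#' probability 1/2) consistently to all masks, resize to the target's
#' dimensions if needed, then alpha-composite onto the target: first the
#' halo layer carrying the perturbed mean donor SR colour, then the
#' saturated highlight layer. Pixels where both soft masks are zero are
#' bit-identical to the target.
#'
#' @param target Target image (H x W x 3 array); receives the highlight.
#' @param source Donor image containing specular reflections.
#' @param cfg A [sr_gen_config()].
#' @param rng A [seeded_rng()] stream.
#' @return A list: `image` (augmented H x W x 3 array) and `mask` (the
#'   transformed binary donor mask at target resolution).
#' @export
generate_sr <- function(target, source, cfg = sr_gen_config(), rng = seeded_rng(0)) {
  validate_image(target); validate_image(source)
  m_s <- extract_sr_mask(source, cfg$threshold)
  if (mask_area_fraction(m_s) < cfg$min_mask_fraction)
    no_donor_error("degenerate donor: SR mask below min_mask_fraction")
  soft <- refine_mask(m_s, cfg$k1, cfg$sigma2)

  rot <- rng_pick(rng, c(0L, 90L, 180L, 270L))
  flips <- rng_bern(rng, 2L)
  highlight <- transform_matrix(soft$highlight, rot, flips[1], flips[2])
  halo <- transform_matrix(soft$halo, rot, flips[1], flips[2])
  mask_t <- transform_matrix(m_s, rot, flips[1], flips[2])

  th <- dim(target)[1]; tw <- dim(target)[2]
  if (!identical(dim(highlight), c(th, tw))) {
    highlight <- pmin(pmax(resize_matrix(highlight, th, tw, bilinear = TRUE), 0), 1)
    halo <- pmin(pmax(resize_matrix(halo, th, tw, bilinear = TRUE), 0), 1)
    mask_t <- resize_matrix(mask_t * 1, th, tw, bilinear = FALSE) > 0.5
  }

  sr_color <- vapply(1:3, function(ch) mean(source[, , ch][m_s]), numeric(1))
  halo_color <- perturb_rgb(sr_color, cfg$perturb_amplitude, rng)

  out <- array(0, dim(target))
  for (ch in 1:3) {
    layer <- (1 - halo) * target[, , ch] + halo * halo_color[ch]
    out[, , ch] <- (1 - highlight) * layer + highlight * cfg$highlight_intensity
  }
  list(image = clip8(out), mask = mask_t)
}

#' Augment a whole manifest by SR generation
#'
#' For every sample, draws `n_per_image` independent same-class donors and
#' writes the generated images (plus their transplanted binary masks) under
#' `out_dir`. Samples with no eligible donor are passed through unchanged
#' with a warning. Labels, boxes and covariates are inherited, so class
#' proportions are preserved exactly.
#'
#' @param m Input manifest.
#' @param cfg A [sr_gen_config()].
#' @param n_per_image Generated images per input image.
#' @param rng A [seeded_rng()] stream.
#' @param out_dir Output directory for PNGs, masks and `manifest.csv`.
#' @param verbose Log one line per processed image.
#' @return The output manifest (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
augment_dataset_gen <- function(m, cfg = sr_gen_config(), n_per_image = 1L,
                                rng = seeded_rng(0), out_dir, verbose = FALSE) {
  validate_manifest(m)
  if (n_per_image < 1L) stop("n_per_image must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eligible <- donor_eligibility(m, cfg)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    target <- read_image(m$image_path[i])
    for (j in seq_len(n_per_image)) {
      out_name <- sprintf("srgen_%04d_%02d.png", i, j)
      out_path <- file.path(out_dir, out_name)
      res <- tryCatch({
        k <- sample_source(m, m$label[i], cfg, rng,
                           exclude_path = m$image_path[i], eligibility = eligible)
        generate_sr(target, read_image(m$image_path[k]), cfg, rng)
      }, specaug_no_donor = function(e) {
        warning("no SR donor for ", m$image_path[i], "; passing through unchanged",
                call. = FALSE)
        NULL
      })
      if (is.null(res)) {
        write_image(target, out_path)
        mask_rel <- NA_character_
      } else {
        write_image(res$image, out_path)
        mask_rel <- sub("\\.png$", "_mask.png", out_path)
        write_mask(res$mask, mask_rel)
      }
      if (verbose) message("srgen: ", m$image_path[i], " -> ", out_path)
      row <- m[i, , drop = FALSE]
      row$image_path <- out_path
      row$sr_mask_path <- mask_rel
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- new_manifest(do.call(rbind, rows))
  write_manifest(out, file.path(out_dir, "manifest.csv"))
  invisible(out)
}
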