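# Shared fixtures and independent brute-force oracles.

# Random 8-bit test image.
random_image <- function(h, w, rng, lo = 0L, hi = 255L) {
  array(rng_int(rng, h * w * 3L, lo, hi), c(h, w, 3L))
}

# Brute-force morphological dilation: for every TRUE pixel, stamp the
# rectangular structuring element (anchor at floor(h/2), floor(w/2)) by an
# explicit double loop. Independent of dilate_mask's shift algebra.
brute_dilate <- function(mask, kh, kw) {
  h <- nrow(mask); w <- ncol(mask)
  ay <- kh %/% 2L; ax <- kw %/% 2L
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    for (dy in (0:(kh - 1L)) - ay) for (dx in (0:(kw - 1L)) - ax) {
      rr <- r + dy; cc <- c + dx
      if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) out[rr, cc] <- TRUE
    }
  }
  out
}

# Exhaustive Mann-Whitney AUC: concordant pairs count 1, ties 1/2.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == "AD"]; neg <- scores[labels != "AD"]
  total <- 0
  for (p in pos) for (n in neg) total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Dense solve of the discrete Laplace equation on the masked pixels with
# the unmasked 4-neighbours as Dirichlet boundary (single channel).
dense_laplace_solve <- function(plane, mask) {
  h <- nrow(plane); w <- ncol(plane)
  idx <- which(mask); n <- length(idx)
  pos <- arrayInd(idx, c(h, w))
  A <- matrix(0, n, n); b <- numeric(n)
  for (i in seq_len(n)) {
    r <- pos[i, 1]; c <- pos[i, 2]; cnt <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > h || cc < 1 || cc > w) next
      cnt <- cnt + 1
      j <- which(pos[, 1] == rr & pos[, 2] == cc)
      if (length(j)) A[i, j] <- A[i, j] + 1 else b[i] <- b[i] + plane[rr, cc]
    }
    A[i, i] <- -cnt
  }
  sol <- solve(A, -b)
  out <- plane
  out[idx] <- sol
  out
}

# 1-D normalized Gaussian kernel (independent of the package's helper).
ref_gauss_kernel <- function(k, sigma) {
  half <- (k - 1) / 2
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w / sum(w)
}

# Small on-disk phantom dataset for manifest-level tests.
make_phantom_dataset <- function(n, size = 64L, seed = 11L,
                                 dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cfg <- phantom_config(n_images = n, image_size = size, seed = seed)
  generate_phantom_set(cfg, dir)
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir), "", names(h))
  h
}
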