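test_that("BT.601 luma conversion matches the closed form", {
  img <- blank_image(1, 3, 0L)
  img[1, 1, ] <- c(255L, 255L, 255L)   # white
  img[1, 2, ] <- c(255L, 0L, 0L)       # pure red: 0.299*255 = 76.245 -> 76
  img[1, 3, ] <- c(10L, 200L, 45L)
  g <- to_grayscale(img)
  expect_identical(g[1, 1], 255L)
  expect_identical(g[1, 2], 76L)
  expect_identical(g[1, 3], as.integer(round(0.299 * 10 + 0.587 * 200 + 0.114 * 45)))

  # neutral grays map to themselves for every level
  levels <- 0:255
  gimg <- array(rep(levels, 3), c(1, 256, 3))
  expect_identical(as.integer(to_grayscale(gimg)), levels)
})

test_that("SR mask thresholding is strict and counts exactly", {
  img <- blank_image(10, 10, 100L)
  expect_equal(sum(extract_sr_mask(blank_image(5, 5, 0L))), 0)

  pts <- cbind(c(1, 2, 3, 4, 5, 9, 10), c(1, 3, 5, 7, 9, 2, 4))
  for (ch in 1:3) for (i in seq_len(nrow(pts))) img[pts[i, 1], pts[i, 2], ch] <- 250L
  expect_equal(sum(extract_sr_mask(img, 245)), 7)

  at245 <- blank_image(3, 3, 245L)
  expect_false(any(extract_sr_mask(at245, 245)))   # strictly greater
  at246 <- blank_image(3, 3, 246L)
  expect_true(all(extract_sr_mask(at246, 245)))
})

test_that("mask extraction is monotone in the threshold", {
  rng <- seeded_rng(12)
  for (i in 1:5) {
    img <- random_image(20, 20, rng)
    prev <- extract_sr_mask(img, 0)
    for (th in c(50, 120, 200, 245, 255)) {
      cur <- extract_sr_mask(img, th)
      expect_true(all(prev | !cur))   # cur subset of prev
      prev <- cur
    }
  }
})

test_that("refine_mask blurs degenerate masks to constants and point masks to Gaussian stamps", {
  empty <- matrix(FALSE, 9, 9)
  r <- refine_mask(empty)
  expect_true(all(r$highlight == 0) && all(r$halo == 0))

  full <- matrix(TRUE, 9, 9)
  r <- refine_mask(full)
  expect_equal(max(abs(r$highlight - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(r$halo - 1)), 0, tolerance = 1e-12)

  point <- matrix(FALSE, 11, 11); point[6, 6] <- TRUE
  r <- refine_mask(point, k1 = 5, sigma2 = 1.0)
  k <- ref_gauss_kernel(5, 0.3 * ((5 - 1) / 2 - 1) + 0.8)
  stamp <- outer(k, k)
  expect_equal(r$highlight[4:8, 4:8], stamp, tolerance = 1e-12)
  expect_equal(sum(r$highlight), 1, tolerance = 1e-12)
  expect_true(all(r$highlight[c(1:3, 9:11), ] == 0))
})

test_that("refine_mask is equivariant under joint 90-degree rotation", {
  rng <- seeded_rng(13)
  mask <- matrix(rng_unif(rng, 15 * 15) > 0.9, 15, 15)
  rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  r <- refine_mask(mask, k1 = 5, sigma2 = 2)
  rr <- refine_mask(transform_mask(mask, 90), k1 = 5, sigma2 = 2)
  expect_equal(rr$highlight, rot90_ccw(r$highlight), tolerance = 1e-12)
  expect_equal(rr$halo, rot90_ccw(r$halo), tolerance = 1e-12)
})

test_that("dilation matches the brute-force double-loop oracle on random masks", {
  rng <- seeded_rng(14)
  for (i in 1:50) {
    h <- rng_int(rng, 1, 4, 32); w <- rng_int(rng, 1, 4, 32)
    mask <- matrix(rng_unif(rng, h * w) > 0.85, h, w)
    kh <- rng_int(rng, 1, 1, 10); kw <- rng_int(rng, 1, 1, 10)
    expect_identical(dilate_mask(mask, kh, kw), brute_dilate(mask, kh, kw))
  }
})

test_that("dilation is extensive, increasing, and exact on a centred point", {
  empty <- matrix(FALSE, 12, 12)
  expect_identical(dilate_mask(empty), empty)

  point <- matrix(FALSE, 30, 30); point[15, 15] <- TRUE
  d <- dilate_mask(point, 10, 10)
  expect_equal(sum(d), 100)
  expect_true(all(which(d, arr.ind = TRUE)[, 1] %in% 10:19))
  expect_true(all(which(d, arr.ind = TRUE)[, 2] %in% 10:19))

  rng <- seeded_rng(15)
  for (i in 1:10) {
    a <- matrix(rng_unif(rng, 256) > 0.9, 16, 16)
    b <- a | matrix(rng_unif(rng, 256) > 0.9, 16, 16)
    da <- dilate_mask(a, 5, 3); db <- dilate_mask(b, 5, 3)
    expect_true(all(da >= a))            # extensive
    expect_true(all(db >= da))           # increasing in the mask argument
    expect_true(sum(da) >= sum(a))
  }
})

test_that("dilation with symmetric odd kernels commutes with rigid transforms", {
  rng <- seeded_rng(16)
  mask <- matrix(rng_unif(rng, 400) > 0.88, 20, 20)
  for (tr in list(list(rot = 180L, fh = FALSE, fv = FALSE),
                  list(rot = 0L, fh = TRUE, fv = FALSE),
                  list(rot = 0L, fh = FALSE, fv = TRUE))) {
    lhs <- dilate_mask(transform_mask(mask, tr$rot, tr$fh, tr$fv), 5, 5)
    rhs <- transform_mask(dilate_mask(mask, 5, 5), tr$rot, tr$fh, tr$fv)
    expect_identical(lhs, rhs)
  }
})

test_that("rigid mask transforms conserve pixels and invert correctly", {
  rng <- seeded_rng(17)
  mask <- matrix(rng_unif(rng, 42) > 0.6, 6, 7)
  expect_identical(transform_mask(transform_mask(mask, 180), 180), mask)
  expect_identical(transform_mask(transform_mask(mask, 0, flip_h = TRUE), 0, flip_h = TRUE), mask)
  expect_identical(transform_mask(transform_mask(mask, 0, flip_v = TRUE), 0, flip_v = TRUE), mask)
  for (rot in c(0L, 90L, 180L, 270L))
    expect_equal(sum(transform_mask(mask, rot)), sum(mask))

  # L-shaped mask on a 4x4 grid: 90 CCW sends (r, c) -> (W - c + 1, r)
  L <- matrix(FALSE, 4, 4); L[1, 1] <- L[2, 1] <- L[2, 2] <- TRUE
  rotated <- transform_mask(L, 90)
  expected <- matrix(FALSE, 4, 4)
  expected[4, 1] <- TRUE; expected[4, 2] <- TRUE; expected[3, 2] <- TRUE
  expect_identical(rotated, expected)
})

test_that("mask area fraction is the true-pixel proportion", {
  expect_equal(mask_area_fraction(matrix(FALSE, 10, 10)), 0)
  expect_equal(mask_area_fraction(matrix(TRUE, 10, 10)), 1)
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  expect_equal(mask_area_fraction(m), 0.25)
})
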