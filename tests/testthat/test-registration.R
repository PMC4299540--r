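test_that("ncc matches the textbook two-pass oracle and its invariances", {
  set.seed(31)
  a <- array(rnorm(216), c(6, 6, 6))
  b <- array(rnorm(216), c(6, 6, 6))
  expect_equal(ncc(a, b), ncc_oracle(a, b), tolerance = 1e-12)
  expect_equal(ncc(a, a), 1, tolerance = 1e-12)
  neg <- 2 * mean(a) - a  # reflection about the mean
  expect_equal(ncc(a, neg), -1, tolerance = 1e-12)
  # invariance under positive affine intensity maps
  expect_equal(ncc(3.7 * a + 42, b), ncc(a, b), tolerance = 1e-10)
  expect_equal(ncc(a, 0.01 * b - 5), ncc(a, b), tolerance = 1e-10)
  expect_error(ncc(array(1, c(3, 3, 3)), b[1:3, 1:3, 1:3]), "zero variance")
  expect_error(ncc(a, b[1:3, 1:3, 1:3]), "shape")
})

test_that("registration recovers planted crops exhaustively", {
  ct <- smooth_vol(c(16, 14, 15), seed = 7, spacing = c(5, 5, 5))
  offsets <- list(c(0L, 0L, 0L), c(7L, 3L, 5L), c(2L, 0L, 4L), c(8L, 6L, 7L))
  for (o in offsets) {
    sub <- ct$data[(o[1] + 1):(o[1] + 8), (o[2] + 1):(o[2] + 8),
                   (o[3] + 1):(o[3] + 8)]
    cbct <- volume3d(sub, spacing = c(5, 5, 5))
    tr <- register_translation(ct, cbct)
    expect_equal(unname(tr$offset_vox), o)
    expect_equal(tr$score, 1, tolerance = 1e-10)
    expect_equal(unname(tr$offset_mm), o * 5)
  }
})

test_that("registration argmax equals the brute-force score map", {
  ct <- rand_vol(c(11, 12, 10), seed = 8, spacing = c(5, 5, 5))
  cbct <- rand_vol(c(6, 5, 7), seed = 9, spacing = c(5, 5, 5))
  tr <- register_translation(ct, cbct)
  m <- ncc_map_oracle(ct$data, cbct$data)
  expect_equal(tr$score, max(m), tolerance = 1e-10)
  best <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_equal(unname(tr$offset_vox), unname(best) - 1L)
})

test_that("registration survives additive noise at moderate SNR", {
  ct <- smooth_vol(c(15, 15, 15), seed = 10, spacing = c(5, 5, 5))
  o <- c(4L, 2L, 6L)
  sub <- ct$data[(o[1] + 1):(o[1] + 8), (o[2] + 1):(o[2] + 8),
                 (o[3] + 1):(o[3] + 8)]
  set.seed(11)
  noisy <- sub + rnorm(length(sub), sd = sd(sub) / 10)
  tr <- register_translation(ct, volume3d(noisy, spacing = c(5, 5, 5)))
  expect_equal(unname(tr$offset_vox), o)
})

test_that("registration rejects degenerate and oversized inputs", {
  flat <- volume3d(array(5, c(10, 10, 10)), spacing = c(5, 5, 5))
  cb <- rand_vol(c(4, 4, 4), seed = 1, spacing = c(5, 5, 5))
  expect_error(register_translation(flat, cb), "zero variance")
  flat_small <- volume3d(array(5, c(3, 3, 3)), spacing = c(5, 5, 5))
  expect_error(register_translation(flat, flat_small), "zero variance")
  big <- rand_vol(c(12, 12, 12), seed = 2, spacing = c(5, 5, 5))
  expect_error(register_translation(cb, big), "nonnegative")
  mixed <- rand_vol(c(6, 6, 6), seed = 3, spacing = c(2, 2, 2))
  expect_error(register_translation(cb, mixed), "same spacing")
})

test_that("GTV mapping into CBCT space is the registration translation", {
  # CT with a bright ball; CBCT is an exact crop starting at index (6, 4, 2)
  dims <- c(24L, 24L, 24L)
  arr <- array(0, dims)
  msk <- sphere_mask(dims, c(12, 13, 11), 4)
  arr[msk] <- 100
  arr <- arr + array(seq(0, 5, length.out = prod(dims)), dims)
  ct <- volume3d(arr)
  g <- tumorloc:::gtv_from_full_mask(msk, c(1, 1, 1), c(0, 0, 0))
  o <- c(6L, 4L, 2L)
  cb <- volume3d(arr[(o[1] + 1):(o[1] + 14), (o[2] + 1):(o[2] + 14),
                     (o[3] + 1):(o[3] + 14)])
  tr <- register_translation(ct, cb)
  expect_equal(unname(tr$offset_vox), o)
  gm <- map_gtv_to_cbct(g, tr, cb)
  expect_equal(unname(gm$bbox[1, ]), unname(g$bbox[1, ]) - o)
  expect_equal(gm$volume_mm3, g$volume_mm3)
  expect_equal(gm$diameter_mm, g$diameter_mm)
  # centroid shifts by exactly -offset_mm (within half a voxel by contract)
  expect_lt(max(abs((gtv_centroid(g) - gtv_centroid(gm)) - tr$offset_mm)),
            0.5)

  # zero offset on co-registered frames: indices unchanged
  tr0 <- register_translation(ct, ct)
  expect_equal(unname(tr0$offset_vox), c(0L, 0L, 0L))
  g0 <- map_gtv_to_cbct(g, tr0, ct)
  expect_equal(g0$bbox, g$bbox)
  expect_error(map_gtv_to_cbct(g, tr, volume3d(array(0, c(4, 4, 4)),
                                               origin = c(200, 200, 200))),
               "outside")
})

test_that("search region is the GTV cuboid dilated and clipped", {
  mk_gtv <- function(lo, hi, dims) {
    full <- array(FALSE, dims)
    full[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- TRUE
    tumorloc:::gtv_from_full_mask(full, c(1, 1, 1), c(0, 0, 0))
  }
  big <- volume3d(array(0, c(256, 256, 256)))
  g <- mk_gtv(c(30, 30, 30), c(40, 40, 40), c(256, 256, 256))
  sr <- build_search_region(g, big, 20L)
  expect_equal(unname(sr$bbox[1, ]), c(10L, 10L, 10L))
  expect_equal(unname(sr$bbox[2, ]), c(60L, 60L, 60L))

  edge <- mk_gtv(c(0, 5, 30), c(6, 12, 40), c(256, 256, 256))
  sre <- build_search_region(edge, big, 20L)
  expect_equal(unname(sre$bbox[1, ]), c(0L, 0L, 10L))

  # monotone in the dilation radius
  sr3 <- build_search_region(g, big, 3L)
  sr5 <- build_search_region(g, big, 5L)
  expect_true(all(sr5$bbox[1, ] <= sr3$bbox[1, ]) &&
                all(sr5$bbox[2, ] >= sr3$bbox[2, ]))
})

test_that("box dilation equals iterated 26-neighbor morphological dilation", {
  dims <- c(30L, 30L, 30L)
  cube <- array(FALSE, dims)
  cube[13:15, 13:16, 14:15] <- TRUE
  dil26 <- function(m) {
    out <- array(FALSE, dim(m))
    idx <- which(m, arr.ind = TRUE)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      sh <- cbind(pmin(pmax(idx[, 1] + dx, 1L), dims[1]),
                  pmin(pmax(idx[, 2] + dy, 1L), dims[2]),
                  pmin(pmax(idx[, 3] + dz, 1L), dims[3]))
      out[sh] <- TRUE
    }
    out
  }
  m <- cube
  for (i in 1:4) m <- dil26(m)
  g <- tumorloc:::gtv_from_full_mask(cube, c(1, 1, 1), c(0, 0, 0))
  sr <- build_search_region(g, volume3d(array(0, dims)), 4L)
  box <- array(FALSE, dims)
  box[(sr$bbox[1, 1] + 1):sr$bbox[2, 1], (sr$bbox[1, 2] + 1):sr$bbox[2, 2],
      (sr$bbox[1, 3] + 1):sr$bbox[2, 3]] <- TRUE
  expect_identical(box, m)
})
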