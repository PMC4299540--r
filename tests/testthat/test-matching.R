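mk_ball_scene <- function(dims = c(40L, 40L, 40L), center = c(20, 20, 20),
                          r = 6) {
  arr <- array(-900, dims)
  msk <- sphere_mask(dims, center, r)
  arr[msk] <- -630
  list(ct = volume3d(arr),
       gtv = tumorloc:::gtv_from_full_mask(msk, c(1, 1, 1), c(0, 0, 0)))
}

test_that("template extraction crops the GTV cuboid, filtered or raw", {
  sc <- mk_ball_scene()
  g <- sc$gtv
  expect_equal(unname(g$bbox[2, ] - g$bbox[1, ]), rep(13L, 3))

  tpl <- extract_template(sc$ct, g, "none")
  expect_equal(dim(tpl$image), dim(g$mask))
  b <- g$bbox
  expect_equal(tpl$image,
               sc$ct$data[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
                          (b[1, 3] + 1):b[2, 3]])

  # padded filtering equals whole-image filtering inside the cuboid
  p <- bse_params(d_mm = g$diameter_mm)
  tplb <- extract_template(sc$ct, g, "bse", p)
  whole <- bse_filter(sc$ct, p)$data
  expect_equal(tplb$image,
               whole[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
                     (b[1, 3] + 1):b[2, 3]], tolerance = 1e-10)

  tpls <- extract_template(sc$ct, g, "sobel")
  wholes <- sobel3d(sc$ct)$data
  expect_equal(tpls$image,
               wholes[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
                      (b[1, 3] + 1):b[2, 3]], tolerance = 1e-10)
})

test_that("template matching finds planted and rescaled copies exactly", {
  img <- smooth_vol(c(20, 20, 24), seed = 23)
  region <- structure(list(
    bbox = rbind(min = c(0L, 0L, 0L), max = dim(img$data)),
    provenance = list()), class = "search_region")
  o <- c(4L, 2L, 9L)
  tpl <- structure(list(
    image = img$data[(o[1] + 1):(o[1] + 7), (o[2] + 1):(o[2] + 7),
                     (o[3] + 1):(o[3] + 7)],
    gtv_mask = array(TRUE, c(7, 7, 7)), mode = "none",
    bbox = rbind(min = c(0L, 0L, 0L), max = c(7L, 7L, 7L)),
    params = NULL), class = "tumor_template")
  mt <- match_template(region, tpl, img)
  expect_equal(unname(mt$offset_vox), o)
  expect_equal(mt$score, 1, tolerance = 1e-10)

  rescaled <- volume3d(3.2 * img$data + 120, img$spacing, img$origin)
  mt2 <- match_template(region, tpl, rescaled)
  expect_equal(unname(mt2$offset_vox), o)
  expect_equal(mt2$score, 1, tolerance = 1e-10)

  flat_tpl <- tpl
  flat_tpl$image <- array(1, c(7, 7, 7))
  expect_error(match_template(region, flat_tpl, img), "degenerate")
  big_tpl <- tpl
  big_tpl$image <- array(1:27000 + 0, c(30, 30, 30))
  expect_error(match_template(region, big_tpl, img), "exceeds")
})

test_that("template matching equals the brute-force score-map oracle", {
  set.seed(29)
  img <- rand_vol(c(12, 11, 12), seed = 29)
  tpl_arr <- array(rnorm(5 * 4 * 5), c(5, 4, 5))
  region <- structure(list(
    bbox = rbind(min = c(0L, 0L, 0L), max = dim(img$data)),
    provenance = list()), class = "search_region")
  tpl <- structure(list(image = tpl_arr, gtv_mask = array(TRUE, dim(tpl_arr)),
                        mode = "none",
                        bbox = rbind(min = c(0L, 0L, 0L), max = dim(tpl_arr)),
                        params = NULL), class = "tumor_template")
  mt <- match_template(region, tpl, img)
  m <- ncc_map_oracle(img$data, tpl_arr)
  expect_equal(mt$score, max(m), tolerance = 1e-10)
  expect_equal(unname(mt$offset_vox),
               unname(which(m == max(m), arr.ind = TRUE)[1, ]) - 1L)
})

test_that("Otsu threshold separates bimodal sets and matches the oracle", {
  vals <- c(rep(-900, 100), rep(-630, 100))
  thr <- otsu_threshold(vals)
  expect_gt(thr, -900)
  expect_lte(thr, -630)
  expect_equal(sum(vals >= thr), 100)

  set.seed(31)
  v <- c(rnorm(250, 0, 1), rnorm(250, 6, 2))
  expect_equal(otsu_threshold(v), otsu_oracle(v), tolerance = 1e-12)
  v2 <- runif(500, -10, 10)
  expect_equal(otsu_threshold(v2), otsu_oracle(v2), tolerance = 1e-12)

  expect_true(is.na(otsu_threshold(rep(3, 10))))
})

test_that("Otsu foreground count is non-increasing in the threshold", {
  set.seed(33)
  v <- rnorm(400)
  counts <- vapply(seq(-2, 2, by = 0.25), function(t) sum(v >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("GTV binarization thresholds inside the placed mask", {
  dims <- c(20L, 20L, 20L)
  arr <- array(-900, dims)
  msk <- sphere_mask(dims, c(10, 10, 10), 5)
  core <- sphere_mask(dims, c(10, 10, 10), 3.5)
  arr[msk] <- -820   # blurred rim
  arr[core] <- -630  # solid core
  vol <- volume3d(arr)
  g <- tumorloc:::gtv_from_full_mask(msk, c(1, 1, 1), c(0, 0, 0))
  bin <- binarize_gtv(vol, g)
  expect_false(bin$fallback)
  expect_true(bin$threshold > -820 && bin$threshold <= -630)
  b <- g$bbox
  expect_identical(bin$foreground,
                   core[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
                        (b[1, 3] + 1):b[2, 3]] & g$mask)
  # binarized set is always a subset of the placed mask
  expect_true(all(!(bin$foreground & !g$mask)))

  flat <- volume3d(array(1, dims))
  expect_warning(binf <- binarize_gtv(flat, g), "constant")
  expect_true(binf$fallback)
  expect_identical(binf$foreground, g$mask)
})

test_that("centroid is the mean world coordinate of the voxel set", {
  expect_equal(centroid(matrix(c(10, 20, 30), 1)), c(10, 20, 30))
  expect_equal(centroid(matrix(c(10, 20, 30), 1), spacing = c(2, 2, 2),
                        origin = c(1, 1, 1)), c(21, 41, 61))

  msk <- sphere_mask(c(40, 40, 40), c(20.5, 19.5, 21), 6)
  cen <- centroid(msk, c(1, 1, 1), c(0, 0, 0))
  expect_lt(max(abs(cen - c(20.5, 19.5, 21))), 0.1)

  set.seed(37)
  pts <- matrix(sample(0:50, 60, replace = TRUE), ncol = 3)
  sp <- c(0.7, 1.1, 2.0); or <- c(-4, 3, 8)
  expect_equal(centroid(pts, sp, or),
               or + colMeans(pts) * sp, tolerance = 1e-12)
  expect_error(centroid(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("localization recovers noiseless planted translations", {
  scene <- lean_scene()
  for (mode in c("none", "sobel", "bse")) {
    res <- lean_localize(scene, shift = c(5, -3, 2), mode = mode)
    err <- sqrt(sum((res$loc$centroid_mm - res$truth)^2))
    expect_lt(err, 1, label = paste("euclidean error, mode", mode))
    # the template comes from the raw CT while the region is preprocessed,
    # so even noiseless scores sit below 1
    expect_gt(res$loc$score, 0.5)
  }
})

test_that("localization is deterministic and translation-equivariant", {
  scene <- lean_scene()
  r1 <- lean_localize(scene, shift = c(3, 2, -4), mode = "bse")
  r2 <- lean_localize(scene, shift = c(3, 2, -4), mode = "bse")
  expect_identical(r1$loc$centroid_mm, r2$loc$centroid_mm)
  expect_identical(r1$loc$offset_vox, r2$loc$offset_vox)

  # integer shifts of the CBCT content move the estimate by the same vector
  base <- lean_localize(scene, shift = c(0, 0, 0), mode = "bse")
  for (s in list(c(4, 0, 0), c(-2, 3, 5))) {
    sh <- lean_localize(scene, shift = s, mode = "bse")
    delta <- sh$loc$centroid_mm - base$loc$centroid_mm
    expect_lt(max(abs(delta - s)), 1e-6)
  }
})
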