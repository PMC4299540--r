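test_that("volume3d validates its invariants", {
  expect_error(volume3d(array(0, c(1, 4, 4))), "at least 2")
  expect_error(volume3d(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(volume3d(matrix(0, 3, 3)), "3D array")
  v <- volume3d(array(1, c(4, 4, 4)), spacing = c(0.5, 0.5, 2),
                origin = c(-10, 0, 5))
  expect_identical(dim(v), c(4L, 4L, 4L))
})

test_that("NIfTI and MetaImage round-trips are value- and metadata-exact", {
  set.seed(42)
  arr <- array(sample(-1000:1000, 16^3, replace = TRUE), c(16, 16, 16))
  v <- volume3d(arr, spacing = c(0.9766, 0.9766, 1.024),
                origin = c(-5, 2.5, 10))
  for (ext in c(".nii.gz", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_identical(v2$data, v$data, info = ext)
    # NIfTI-1 stores pixdim/offsets as 32-bit floats; MetaImage as text
    tol <- if (ext == ".nii.gz") 1e-6 else 1e-12
    expect_equal(v2$spacing, v$spacing, tolerance = tol, info = ext)
    expect_equal(v2$origin, v$origin, tolerance = tol, info = ext)
    unlink(f)
  }
  # constant-valued volume round-trip
  f <- tempfile(fileext = ".mha")
  vc <- volume3d(array(100, c(16, 16, 16)))
  write_volume(vc, f)
  expect_identical(read_volume(f)$data, vc$data)
  unlink(f)
})

test_that("MetaImage spacing is taken from the header", {
  f <- tempfile(fileext = ".mha")
  v <- volume3d(array(0L + 1:27, c(3, 3, 3)),
                spacing = c(0.9766, 0.9766, 1.024))
  write_volume(v, f)
  hdr <- readLines(f, n = 9, warn = FALSE)
  expect_true(any(grepl("^ElementSpacing = 0.9766 0.9766 1.024", hdr)))
  expect_equal(read_volume(f)$spacing, c(0.9766, 0.9766, 1.024))
  unlink(f)
})

test_that("corrupt volume files raise format errors, never partial volumes", {
  f <- tempfile(fileext = ".mha")
  v <- volume3d(array(1:64 + 0, c(4, 4, 4)))
  write_volume(v, f)
  full <- readBin(f, "raw", file.size(f))
  writeBin(full[1:(length(full) - 40)], f)
  expect_error(read_volume(f), "truncated")
  writeBin(full[1:30], f)
  expect_error(read_volume(f))
  expect_error(read_volume(tempfile(fileext = ".nii")), "does not exist")
  # header missing a required field
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 4 4 4",
               "ElementType = MET_SHORT", "ElementDataFile = LOCAL"), f)
  expect_error(read_volume(f), "ElementSpacing")
  unlink(f)
})

test_that("contour voxelization recovers box and sphere volumes", {
  target <- volume3d(array(0, c(20, 20, 20)))
  sq <- cbind(c(4.5, 14.5, 14.5, 4.5), c(4.5, 4.5, 14.5, 14.5))
  contours <- list(slices = lapply(8:12, function(z)
    list(z_mm = z, points_mm = sq)))
  g <- contours_to_mask(contours, target)
  expect_equal(g$volume_mm3, 500)
  expect_equal(unname(g$bbox[1, ]), c(5L, 5L, 8L))
  expect_equal(unname(g$bbox[2, ]), c(15L, 15L, 13L))

  # generic-position center: no voxel centers exactly on the sphere surface
  sph <- make_sphere_contours(c(10.2, 10.3, 10.4), 10)
  gs <- contours_to_mask(sph, target)
  expect_lt(abs(gs$volume_mm3 - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.03)
  expect_equal(gs$isocenter_mm, c(10.2, 10.3, 10.4))

  degenerate <- list(slices = list(list(
    z_mm = 10, points_mm = cbind(c(5, 5, 5), c(5, 5, 5)))))
  expect_error(contours_to_mask(degenerate, target), "empty")
})

test_that("contour voxelization of a sphere's own boundary overlaps >= 95%", {
  target <- volume3d(array(0, c(24, 24, 24)))
  for (d in c(8, 10, 12)) {
    truth <- sphere_mask(c(24, 24, 24), c(11.5, 11.5, 11.5), d / 2)
    g <- contours_to_mask(make_sphere_contours(c(11.5, 11.5, 11.5), d),
                          target)
    full <- array(FALSE, c(24, 24, 24))
    full[(g$bbox[1, 1] + 1):g$bbox[2, 1], (g$bbox[1, 2] + 1):g$bbox[2, 2],
         (g$bbox[1, 3] + 1):g$bbox[2, 3]] <- g$mask
    overlap <- sum(full & truth) / sum(full | truth)
    expect_gte(overlap, 0.95)
  }
})

test_that("isotropic resampling reproduces grids, constants and cubics", {
  v <- rand_vol(c(10, 10, 10), seed = 7)
  same <- resample_isotropic(v, 1, method = "tricubic")
  expect_equal(same$data, v$data, tolerance = 1e-12)

  vc <- volume3d(array(42, c(8, 8, 8)), spacing = c(2, 2, 2))
  out <- resample_isotropic(vc, 1, method = "trilinear")
  expect_true(all(abs(out$data - 42) < 1e-12))

  # tricubic interpolation is exact on polynomials of degree <= 3
  dims <- c(12, 12, 12)
  xw <- (0:11) * 2; yw <- (0:11) * 2; zw <- (0:11) * 2
  ramp <- outer(outer(2 * xw, 3 * yw, "+"), -zw, "+")
  vr <- volume3d(ramp, spacing = c(2, 2, 2))
  fine <- resample_isotropic(vr, 1, method = "tricubic")
  fd <- dim(fine$data)
  xf <- (0:(fd[1] - 1)); yf <- (0:(fd[2] - 1)); zf <- (0:(fd[3] - 1))
  want <- outer(outer(2 * xf, 3 * yf, "+"), -zf, "+")
  interior <- 5:18
  got <- fine$data[interior, interior, interior]
  ref <- want[interior, interior, interior]
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-6)

  expect_error(resample_isotropic(v, 100), "exceeds the volume extent")
})

test_that("down-up resampling round-trip recovers smooth volumes inside", {
  dims <- c(17, 17, 17)
  xw <- 0:16
  ramp <- outer(outer(2 * xw, 3 * xw, "+"), -xw, "+")
  v <- volume3d(ramp, spacing = c(1, 1, 1))
  down <- resample_isotropic(v, 2, method = "tricubic")
  up <- resample_isotropic(down, 1, method = "tricubic")
  interior <- 4:13
  expect_lt(max(abs(up$data[interior, interior, interior] -
                      v$data[interior, interior, interior])), 1e-6)
})
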