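# Fixture builders and independent brute-force oracles used across the suite.

rand_vol <- function(dims, seed, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     sd = 100) {
  set.seed(seed)
  volume3d(array(rnorm(prod(dims), sd = sd), dim = dims), spacing, origin)
}

# Smooth random volume (sum of a few low-frequency cosines) so that planted
# registration optima are unique.
smooth_vol <- function(dims, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  x <- seq(0, 1, length.out = dims[1])
  y <- seq(0, 1, length.out = dims[2])
  z <- seq(0, 1, length.out = dims[3])
  arr <- array(0, dims)
  for (i in 1:4) {
    f <- runif(3, 0.5, 3)
    ph <- runif(3, 0, 2 * pi)
    a <- rnorm(1, sd = 50)
    arr <- arr + a * outer(outer(cos(2 * pi * f[1] * x + ph[1]),
                                 cos(2 * pi * f[2] * y + ph[2])),
                           cos(2 * pi * f[3] * z + ph[3]))
  }
  volume3d(arr + array(rnorm(prod(dims), sd = 2), dims), spacing)
}

# Voxel-center rasterized sphere mask on a grid with given spacing/origin.
sphere_mask <- function(dims, center, radius, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  xw <- origin[1] + (0:(dims[1] - 1)) * spacing[1]
  yw <- origin[2] + (0:(dims[2] - 1)) * spacing[2]
  zw <- origin[3] + (0:(dims[3] - 1)) * spacing[3]
  d2 <- outer(outer((xw - center[1])^2, (yw - center[2])^2, "+"),
              (zw - center[3])^2, "+")
  array(d2 <= radius^2, dims)
}

# Gaussian blob I(p) = A exp(-|p - c|^2 / (2 a^2)) on the voxel grid.
gaussian_blob <- function(dims, center, a, A = 100, spacing = c(1, 1, 1)) {
  xw <- (0:(dims[1] - 1)) * spacing[1]
  yw <- (0:(dims[2] - 1)) * spacing[2]
  zw <- (0:(dims[3] - 1)) * spacing[3]
  d2 <- outer(outer((xw - center[1])^2, (yw - center[2])^2, "+"),
              (zw - center[3])^2, "+")
  volume3d(A * exp(-d2 / (2 * a^2)), spacing)
}

# Two-pass textbook NCC (population SDs).
ncc_oracle <- function(t, f) {
  n <- length(t)
  tm <- sum(t) / n
  fm <- sum(f) / n
  st <- sqrt(sum((t - tm)^2) / n)
  sf <- sqrt(sum((f - fm)^2) / n)
  sum((t - tm) * (f - fm)) / (n * st * sf)
}

# Brute-force neighborhood-sort median filter with edge replication.
median_oracle <- function(arr, size = 3L) {
  dims <- dim(arr)
  r <- (size - 1L) %/% 2L
  out <- array(NA_real_, dims)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    xs <- pmin(pmax(x + (-r:r), 1L), dims[1])
    ys <- pmin(pmax(y + (-r:r), 1L), dims[2])
    zs <- pmin(pmax(z + (-r:r), 1L), dims[3])
    out[x, y, z] <- median(arr[xs, ys, zs])
  }
  out
}

# Dense 3D correlation with an arbitrary kernel, edge replication.
conv3_oracle <- function(arr, ker) {
  dims <- dim(arr)
  kd <- dim(ker)
  r <- (kd - 1L) %/% 2L
  out <- array(0, dims)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    xs <- pmin(pmax(x + (-r[1]:r[1]), 1L), dims[1])
    ys <- pmin(pmax(y + (-r[2]:r[2]), 1L), dims[2])
    zs <- pmin(pmax(z + (-r[3]:r[3]), 1L), dims[3])
    out[x, y, z] <- sum(arr[xs, ys, zs] * ker)
  }
  out
}

sep_kernel3 <- function(kx, ky, kz) {
  outer(outer(kx, ky), kz)
}

# Exhaustive Otsu: maximize between-class variance over all bin cuts.
otsu_oracle <- function(values, bins = 256L) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  h <- tabulate(pmin(pmax(findInterval(values, breaks,
                                       rightmost.closed = TRUE), 1L), bins),
                nbins = bins)
  best <- -Inf
  best_t <- NA
  for (t in 1:(bins - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):bins] * mids[(t + 1):bins]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) {
      best <- sb
      best_t <- t
    }
  }
  breaks[best_t + 1L]
}

# Brute-force NCC score map (R-level sliding window).
ncc_map_oracle <- function(img, tpl) {
  id <- dim(img); td <- dim(tpl)
  od <- id - td + 1L
  out <- array(NA_real_, od)
  for (z in 1:od[3]) for (y in 1:od[2]) for (x in 1:od[1]) {
    win <- img[x:(x + td[1] - 1), y:(y + td[2] - 1), z:(z + td[3] - 1)]
    out[x, y, z] <- ncc_oracle(tpl, win)
  }
  out
}

# A compact noiseless localization scenario: an 80^3 CT containing one
# spherical tumor in a dark background, its GTV, and a helper producing a
# shifted zero-degradation CBCT fraction.
lean_scene <- function(tumor_center = c(40, 40, 40), diameter = 12) {
  spec <- list(center = tumor_center, d = diameter)
  dims <- c(80L, 80L, 80L)
  arr <- array(-900, dims)
  msk <- sphere_mask(dims, tumor_center, diameter / 2)
  arr[msk] <- -630
  ct <- volume3d(arr, c(1, 1, 1), c(0, 0, 0))
  gtv <- tumorloc:::gtv_from_full_mask(msk, c(1, 1, 1), c(0, 0, 0),
                                       isocenter_mm = tumor_center)
  list(ct = ct, gtv = gtv, center = tumor_center)
}

lean_fraction <- function(scene, shift = c(0, 0, 0), fov = 48) {
  ds <- degradation_spec(blur_fwhm_mm = 0, noise_sd = 0, contrast_scale = 1,
                         shift_mm = shift, fov_mm = fov,
                         isocenter_mm = scene$center)
  degrade_to_cbct(scene$ct, ds)
}

lean_localize <- function(scene, shift, mode = "bse", fov = 48) {
  dg <- lean_fraction(scene, shift, fov)
  ct5 <- resample_isotropic(scene$ct, 4, method = "trilinear")
  cb5 <- resample_isotropic(dg$cbct, 4, method = "trilinear")
  tr <- register_translation(ct5, cb5)
  cfg <- default_config()
  cfg$enhance$mode <- mode
  loc <- localize(scene$ct, dg$cbct, scene$gtv, tr, cfg)
  list(loc = loc, truth = scene$center + shift)
}
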