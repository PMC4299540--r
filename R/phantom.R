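# Geometry of the digital thorax phantom (mm, world = voxel index at 1 mm):
# an elliptical soft-tissue body cylinder in air, two ellipsoidal lung fields
# at -900 HU, and anti-aliased spherical tumors at lung + 270 HU. The layout
# is sized so a 128 mm cubic CBCT field of view centered on any tumor
# station stays inside the CT grid.
phantom_geometry <- function(dim = c(220L, 200L, 240L), spacing = 1) {
  cx <- (dim[1] - 1) * spacing / 2
  cy <- (dim[2] - 1) * spacing / 2
  list(dim = as.integer(dim), spacing = spacing,
       body_center = c(cx, cy), body_semi = c(100, 88) * spacing / 1,
       lung_centers = list(right = c(cx - 50, cy, 120),
                           left = c(cx + 50, cy, 120)),
       lung_semi = c(38, 62, 75),
       # station levels sit at generic (non-grid-aligned) coordinates so
       # that rasterized spheres carry no voxel centers exactly on their
       # surface, which would bias voxel-counted volumes
       level_z = c(upper = 165.2, middle = 120.3, lower = 76.2))
}

#' World coordinate of a tumor station in the digital phantom
#'
#' Stations are named by lung side and craniocaudal level (`upper` ~ apex,
#' `middle` ~ tracheal-bifurcation level, `lower` ~ base). With
#' `wall = TRUE` the sphere center is moved along x toward the lateral lung
#' boundary until the sphere surface sits `wall_gap_mm` inside it
#' (`wall_gap_mm = 0` means attached, a positive gap means "close to" the
#' wall).
#'
#' @param side `"right"` or `"left"` lung.
#' @param level `"upper"`, `"middle"` or `"lower"`.
#' @param wall logical; place the tumor at the mediastinal lung wall.
#' @param diameter_mm tumor diameter (needed when `wall = TRUE`).
#' @param wall_gap_mm gap between the sphere surface and the lung boundary
#'   when `wall = TRUE`; 0 = attached.
#' @param geom phantom geometry (internal default).
#' @return numeric length-3 station coordinate in mm.
#' @export
phantom_station <- function(side = c("right", "left"),
                            level = c("upper", "middle", "lower"),
                            wall = FALSE, diameter_mm = 10,
                            wall_gap_mm = 0,
                            geom = phantom_geometry()) {
  side <- match.arg(side)
  level <- match.arg(level)
  z <- geom$level_z[[level]]
  lc <- geom$lung_centers[[side]]
  y <- lc[2] + 0.1
  if (!wall) {
    # 20.8 mm medial of the lung center, well inside the lung field
    x <- lc[1] + if (side == "right") 20.8 else -20.8
  } else {
    s <- sqrt(1 - ((z - lc[3]) / geom$lung_semi[3])^2)
    wx <- geom$lung_semi[1] * s
    r <- diameter_mm / 2 + wall_gap_mm
    x <- lc[1] + if (side == "right") (wx - r) else -(wx - r)
  }
  c(x, y, z)
}

#' Specification of the digital lung phantom
#'
#' Defaults reproduce the validation layout: three 10 mm spherical tumors
#' (lung -900 HU, tumor contrast +270 HU) at the apex, tracheal-bifurcation
#' level and base of the lung fields.
#'
#' @param dim voxel grid dimensions.
#' @param spacing isotropic voxel size in mm.
#' @param lung_hu,contrast_hu,body_hu,air_hu tissue intensities (HU).
#' @param tumors list of `list(center = c(x,y,z) mm, diameter_mm = d)`;
#'   default three 10 mm spheres at the apex / bifurcation / base stations.
#' @param supersample per-axis subsampling factor for anti-aliased sphere
#'   rasterization (default 3, i.e. 27 subsamples per voxel).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(220L, 200L, 240L), spacing = 1,
                         lung_hu = -900, contrast_hu = 270, body_hu = 40,
                         air_hu = -1000, tumors = NULL, supersample = 3L) {
  geom <- phantom_geometry(dim, spacing)
  if (is.null(tumors)) {
    tumors <- list(
      apex = list(center = phantom_station("right", "upper", geom = geom),
                  diameter_mm = 10),
      bifurcation = list(center = phantom_station("left", "middle",
                                                  geom = geom),
                         diameter_mm = 10),
      base = list(center = phantom_station("right", "lower", geom = geom),
                  diameter_mm = 10))
  }
  for (tm in tumors) {
    if (tm$diameter_mm <= 2 * spacing)
      stop("tumor diameter must exceed twice the voxel size")
  }
  structure(list(dim = as.integer(dim), spacing = spacing, geom = geom,
                 lung_hu = lung_hu, contrast_hu = contrast_hu,
                 body_hu = body_hu, air_hu = air_hu, tumors = tumors,
                 supersample = as.integer(supersample)),
            class = "phantom_spec")
}

inside_lung <- function(p, geom, slack = 1e-6) {
  any(vapply(geom$lung_centers, function(lc) {
    sum(((p - lc) / (geom$lung_semi))^2) <= 1 + slack
  }, logical(1)))
}

#' Generate the digital lung-phantom planning CT
#'
#' Rasterizes the phantom: air background, elliptical soft-tissue body,
#' two ellipsoidal lung fields, and anti-aliased spherical tumors at
#' `lung_hu + contrast_hu`. Tumor GTV masks (voxel centers within the
#' sphere, via >= 50% subsample occupancy) and the exact analytic sphere
#' centers are returned as ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct` ([volume3d()]), `gtvs` (named list of
#'   [gtv_structure()], isocenter at the station), and `truth` (matrix of
#'   analytic tumor centers, mm).
#' @export
make_phantom_ct <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geom
  nd <- spec$dim
  sp <- spec$spacing
  xw <- (0:(nd[1] - 1)) * sp
  yw <- (0:(nd[2] - 1)) * sp
  zw <- (0:(nd[3] - 1)) * sp
  body2d <- outer(((xw - g$body_center[1]) / g$body_semi[1])^2,
                  ((yw - g$body_center[2]) / g$body_semi[2])^2, "+") <= 1
  slice <- ifelse(body2d, spec$body_hu, spec$air_hu)
  arr <- array(rep(slice, nd[3]), dim = nd)
  for (lc in g$lung_centers) {
    base2d <- outer(((xw - lc[1]) / g$lung_semi[1])^2,
                    ((yw - lc[2]) / g$lung_semi[2])^2, "+")
    dz2 <- ((zw - lc[3]) / g$lung_semi[3])^2
    for (k in which(dz2 < 1)) {
      m <- base2d <= (1 - dz2[k])
      sl <- arr[, , k]
      sl[m] <- spec$lung_hu
      arr[, , k] <- sl
    }
  }
  ss <- spec$supersample
  offs <- ((seq_len(ss) - (ss + 1) / 2) / ss) * sp
  gtvs <- list()
  truth <- matrix(NA_real_, length(spec$tumors), 3,
                  dimnames = list(names(spec$tumors), c("x", "y", "z")))
  for (ti in seq_along(spec$tumors)) {
    tm <- spec$tumors[[ti]]
    ctr <- tm$center
    r <- tm$diameter_mm / 2
    if (!inside_lung(ctr, g))
      stop("tumor station (", paste(format(ctr), collapse = ", "),
           ") lies outside the lung fields")
    lo <- pmax(as.integer(floor((ctr - r) / sp)) - 1L, 0L)
    hi <- pmin(as.integer(ceiling((ctr + r) / sp)) + 1L, nd - 1L)
    bx <- (lo[1]:hi[1]) * sp
    by <- (lo[2]:hi[2]) * sp
    bz <- (lo[3]:hi[3]) * sp
    bd <- c(length(bx), length(by), length(bz))
    frac <- array(0, bd)
    for (oz in offs) for (oy in offs) for (ox in offs) {
      d2 <- outer(outer((bx + ox - ctr[1])^2, (by + oy - ctr[2])^2, "+"),
                  (bz + oz - ctr[3])^2, "+")
      frac <- frac + (d2 <= r^2)
    }
    frac <- frac / ss^3
    sub <- arr[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
               (lo[3] + 1):(hi[3] + 1)]
    tumor_val <- spec$lung_hu + frac * spec$contrast_hu
    sel <- frac > 0
    sub[sel] <- pmax(sub[sel], tumor_val[sel])
    arr[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
        (lo[3] + 1):(hi[3] + 1)] <- sub
    mask_box <- frac >= 0.5
    idx <- which(mask_box, arr.ind = TRUE)
    mlo <- apply(idx, 2, min); mhi <- apply(idx, 2, max)
    gtv <- gtv_structure(mask_box[mlo[1]:mhi[1], mlo[2]:mhi[2],
                                  mlo[3]:mhi[3], drop = FALSE],
                         rbind(min = lo + mlo - 1L, max = lo + mhi),
                         rep(sp, 3), c(0, 0, 0), isocenter_mm = ctr)
    nm <- names(spec$tumors)[ti]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("tumor", ti)
    gtvs[[nm]] <- gtv
    truth[ti, ] <- ctr
  }
  list(ct = volume3d(arr, rep(sp, 3), c(0, 0, 0)), gtvs = gtvs,
       truth = truth, spec = spec)
}

#' Specification of the MV-CBCT degradation model
#'
#' The degradation emulates the qualitative character of megavoltage CBCT
#' relative to planning CT: reduced soft-tissue contrast, blur from the
#' imaging chain, and additive noise, together with a known rigid patient
#' translation. Defaults: blur FWHM 3 mm, noise SD 30 image units, contrast
#' scale 0.6, shift (4, -3, 6) mm, 128 mm cubic field of view.
#'
#' @param blur_fwhm_mm Gaussian blur FWHM in mm, >= 0.
#' @param noise_sd additive Gaussian noise SD in image units, >= 0.
#' @param contrast_scale contrast scale factor about the lung baseline,
#'   in (0, 1].
#' @param shift_mm applied rigid translation (mm) of the anatomy.
#' @param fov_mm edge length of the cubic CBCT field of view (mm).
#' @param isocenter_mm world coordinate the FOV is centered on.
#' @param seed RNG seed for the noise realization.
#' @param baseline_hu intensity about which contrast is scaled.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(blur_fwhm_mm = 3, noise_sd = 30,
                             contrast_scale = 0.6, shift_mm = c(4, -3, 6),
                             fov_mm = 128, isocenter_mm = NULL, seed = NULL,
                             baseline_hu = -900) {
  if (blur_fwhm_mm < 0) stop("blur FWHM must be >= 0")
  if (noise_sd < 0) stop("noise SD must be >= 0")
  if (contrast_scale <= 0 || contrast_scale > 1)
    stop("contrast scale must be in (0, 1]")
  structure(list(blur_fwhm_mm = blur_fwhm_mm, noise_sd = noise_sd,
                 contrast_scale = contrast_scale,
                 shift_mm = as.numeric(shift_mm), fov_mm = fov_mm,
                 isocenter_mm = isocenter_mm, seed = seed,
                 baseline_hu = baseline_hu),
            class = "degradation_spec")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Degrade a planning CT into a simulated MV-CBCT fraction
#'
#' Applies, in order: contrast scaling about the lung baseline, rigid
#' translation of the anatomy by `shift_mm` (tricubic resampling), Gaussian
#' blur, and seeded additive Gaussian noise, then crops to the cubic field
#' of view centered on the isocenter. The applied shift is recorded exactly:
#' a structure at CT world coordinate `w` appears at `w + shift_mm` in the
#' CBCT frame.
#'
#' @param ct a planning-CT [volume3d()] (isotropic).
#' @param d a [degradation_spec()] with `isocenter_mm` set.
#' @return list with `cbct` ([volume3d()]), `applied_shift_mm`, and the spec.
#' @export
degrade_to_cbct <- function(ct, d) {
  stopifnot(inherits(ct, "volume3d"), inherits(d, "degradation_spec"))
  if (!vol_is_isotropic(ct)) stop("planning CT must be isotropic")
  if (is.null(d$isocenter_mm)) stop("degradation spec needs an isocenter")
  sp <- ct$spacing[1]
  extent <- (dim(ct$data) - 1) * sp
  if (any(d$fov_mm > extent))
    stop("CBCT field of view (", d$fov_mm, " mm) exceeds the CT extent")
  n <- as.integer(round(d$fov_mm / sp))
  origin <- d$isocenter_mm - (n - 1) / 2 * sp
  sigma_mm <- d$blur_fwhm_mm / (2 * sqrt(2 * log(2)))
  padv <- if (d$blur_fwhm_mm > 0)
    as.integer(ceiling(4 * sigma_mm / sp)) else 0L
  vol <- resample_to_grid(ct, rep(n + 2L * padv, 3), rep(sp, 3),
                          origin - padv * sp, shift_mm = d$shift_mm,
                          method = "tricubic")
  arr <- d$baseline_hu + d$contrast_scale * (vol$data - d$baseline_hu)
  if (d$blur_fwhm_mm > 0) {
    gk <- gauss_kernel(sigma_mm / sp, 0L)
    arr <- cpp_sepconv3(arr, dim(arr), gk, gk, gk)
  }
  if (padv > 0L)
    arr <- arr[(padv + 1):(padv + n), (padv + 1):(padv + n),
               (padv + 1):(padv + n)]
  if (d$noise_sd > 0)
    arr <- arr + with_seed(d$seed,
                           array(stats::rnorm(length(arr), 0, d$noise_sd),
                                 dim = dim(arr)))
  list(cbct = volume3d(arr, rep(sp, 3), origin),
       applied_shift_mm = d$shift_mm, spec = d)
}

#' Generate clinical-like simulated cases
#'
#' Ten (by default) single-tumor cases whose effective diameters cycle
#' through the clinical table ([table1_diameters()]), with stations
#' distributed 5 upper / 2 middle / 3 lower across the two lungs and two
#' tumors close to or attached to the lung wall (one attached, one 3 mm from
#' the boundary), each with four CBCT fractions at random continuous
#' (sub-voxel) rigid shifts. All ground truth (station, shift,
#' per-fraction noise seed) is recorded; the case list is a deterministic
#' function of the seed.
#'
#' @param n number of cases, default 10.
#' @param diameters effective diameters (mm) to cycle through.
#' @param seed master seed; fraction shifts and noise seeds derive from it.
#' @param n_fractions CBCT fractions per case, default 4.
#' @param shift_range_mm fraction shifts are uniform in
#'   `[-shift_range_mm, shift_range_mm]` per axis, default 6.
#' @return list of case descriptors: `id`, `diameter_mm`, `side`, `level`,
#'   `wall`, `station_mm`, and `fractions` (list of `shift_mm`, `seed`).
#' @export
make_clinical_like_cases <- function(n = 10L, diameters = table1_diameters(),
                                     seed = 1L, n_fractions = 4L,
                                     shift_range_mm = 6) {
  stopifnot(n >= 1L)
  sides <- c("left", "left", "right", "right", "right",
             "right", "right", "left", "right", "right")
  levels <- c("upper", "middle", "middle", "upper", "upper",
              "lower", "lower", "upper", "upper", "lower")
  walls <- seq_len(10) %in% c(6L, 8L)
  # one wall tumor attached (case 6), one merely close to the wall (case 8)
  wall_gaps <- ifelse(seq_len(10) == 8L, 3, 0)
  shifts <- with_seed(seed,
    array(stats::runif(n * n_fractions * 3, -shift_range_mm,
                       shift_range_mm),
          dim = c(3, n_fractions, n)))
  lapply(seq_len(n), function(i) {
    j <- ((i - 1L) %% 10L) + 1L
    d <- diameters[((i - 1L) %% length(diameters)) + 1L]
    station <- phantom_station(sides[j], levels[j], wall = walls[j],
                               diameter_mm = d, wall_gap_mm = wall_gaps[j])
    fractions <- lapply(seq_len(n_fractions), function(f) {
      list(shift_mm = shifts[, f, i],
           seed = (abs(as.integer(seed)) %% 100000L) * 10000L +
             i * 100L + f)
    })
    list(id = i, diameter_mm = d, side = sides[j], level = levels[j],
         wall = walls[j], station_mm = station, fractions = fractions)
  })
}

#' Axial circle contours for a spherical tumor
#'
#' Convenience generator for the JSON contour dialect: per-slice regular
#' polygons approximating the circular cross-sections of a sphere.
#'
#' @param center_mm sphere center (mm).
#' @param diameter_mm sphere diameter (mm).
#' @param slice_spacing_mm axial slice spacing (mm), default 1.
#' @param n_vertices polygon vertices per slice, default 72.
#' @return a contour list usable by [contours_to_mask()].
#' @export
make_sphere_contours <- function(center_mm, diameter_mm,
                                 slice_spacing_mm = 1, n_vertices = 72L) {
  r <- diameter_mm / 2
  z0 <- center_mm[3]
  ks <- seq(ceiling((z0 - r) / slice_spacing_mm),
            floor((z0 + r) / slice_spacing_mm))
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  slices <- list()
  for (k in ks) {
    z <- k * slice_spacing_mm
    rho2 <- r^2 - (z - z0)^2
    if (rho2 <= 0) next
    rho <- sqrt(rho2)
    slices[[length(slices) + 1L]] <-
      list(z_mm = z, points_mm = cbind(center_mm[1] + rho * cos(theta),
                                       center_mm[2] + rho * sin(theta)))
  }
  list(slices = slices, isocenter_mm = center_mm)
}
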