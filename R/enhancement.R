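#' Effective diameter of a GTV
#'
#' The diameter of the sphere whose volume equals the GTV volume,
#' `d = 2 (3 V / 4 pi)^(1/3)`. A quarter of this diameter sets the Gaussian
#' scale of the blob-structure-enhancement filter.
#'
#' @param V_GTV volume in mm^3, > 0.
#' @return effective diameter in mm.
#' @export
effective_diameter <- function(V_GTV) {
  if (!is.numeric(V_GTV) || any(!is.finite(V_GTV)) || any(V_GTV <= 0))
    stop("GTV volume must be positive and finite")
  2 * (3 * V_GTV / (4 * pi))^(1 / 3)
}

#' Parameters of the blob-structure-enhancement filter
#'
#' @param sigma_mm Gaussian scale in mm; if `NULL`, derived as `d_mm / 4`.
#' @param gamma sharpness-of-selectivity exponent, default 1.
#' @param d_mm GTV effective diameter in mm (used when `sigma_mm` is `NULL`).
#' @return an object of class `bse_params`.
#' @export
bse_params <- function(sigma_mm = NULL, gamma = 1, d_mm = NULL) {
  if (is.null(sigma_mm)) {
    if (is.null(d_mm)) stop("either `sigma_mm` or `d_mm` must be given")
    sigma_mm <- d_mm / 4
  }
  if (sigma_mm <= 0) stop("`sigma_mm` must be positive")
  if (gamma <= 0) stop("`gamma` must be positive")
  structure(list(sigma_mm = sigma_mm, gamma = gamma, d_mm = d_mm),
            class = "bse_params")
}

#' 3D Sobel gradient magnitude
#'
#' Edge enhancement with the three 3x3x3 Sobel kernels (central difference
#' along one axis, (1,2,1) smoothing along the other two); the output is the
#' Euclidean norm of the three directional responses. Borders are
#' edge-replicated.
#'
#' @param v a [volume3d()].
#' @return gradient-magnitude [volume3d()].
#' @export
sobel3d <- function(v) {
  stopifnot(inherits(v, "volume3d"))
  d <- c(-1, 0, 1)
  s <- c(1, 2, 1)
  gx <- sepconv(v$data, d, s, s)
  gy <- sepconv(v$data, s, d, s)
  gz <- sepconv(v$data, s, s, d)
  volume3d(sqrt(gx^2 + gy^2 + gz^2), v$spacing, v$origin)
}

#' Hessian eigenvalue field at a Gaussian scale
#'
#' Computes the six distinct second Gaussian-derivative responses of the
#' volume at scale `sigma_mm`, assembles the symmetric Hessian at every voxel
#' and returns its eigenvalues sorted `l1 >= l2 >= l3`. For a bright blob all
#' three are negative; for a bright tube `l1 ~ 0 > l2, l3`; for a bright
#' plate `l1, l2 ~ 0 > l3`.
#'
#' @param v an isotropic [volume3d()].
#' @param sigma_mm Gaussian scale in mm; must be at least half a voxel.
#' @return an object of class `hessian_eigenvalues`: list of arrays
#'   `l1`, `l2`, `l3` plus the scale used.
#' @export
hessian_field <- function(v, sigma_mm) {
  stopifnot(inherits(v, "volume3d"))
  if (!vol_is_isotropic(v))
    stop("hessian_field requires an isotropic volume")
  sp <- v$spacing[1]
  if (!is.numeric(sigma_mm) || sigma_mm < 0.5 * sp)
    stop("sigma_mm = ", sigma_mm, " mm is below resolvability ",
         "(need at least half the voxel size, ", 0.5 * sp, " mm)")
  s <- sigma_mm / sp
  g <- gauss_kernel(s, 0L)
  d1 <- gauss_kernel(s, 1L)
  d2 <- gauss_kernel(s, 2L)
  # second derivatives carry 1/spacing^2 so eigenvalues are per mm^2
  f <- 1 / sp^2
  xx <- sepconv(v$data, d2, g, g) * f
  yy <- sepconv(v$data, g, d2, g) * f
  zz <- sepconv(v$data, g, g, d2) * f
  xy <- sepconv(v$data, d1, d1, g) * f
  xz <- sepconv(v$data, d1, g, d1) * f
  yz <- sepconv(v$data, g, d1, d1) * f
  e <- cpp_eig3sym(xx, yy, zz, xy, xz, yz)
  dm <- dim(v$data)
  structure(list(l1 = array(e$l1, dm), l2 = array(e$l2, dm),
                 l3 = array(e$l3, dm), sigma_mm = sigma_mm,
                 spacing = v$spacing, origin = v$origin),
            class = "hessian_eigenvalues")
}

#' Blob-structure-enhancement (BSE) filter
#'
#' Selectively enhances bright sphere-like structures: wherever the ordered
#' Hessian eigenvalues satisfy the blob condition `l3 <= l2 <= l1 < 0` the
#' output is `|l3| (l2/l3)^gamma (l1/l2)^gamma` (which telescopes to `|l1|`
#' at gamma = 1), and 0 elsewhere. Plates and tubes, whose leading
#' eigenvalue is near zero, are suppressed; the output is nonnegative
#' everywhere.
#'
#' @param v an isotropic [volume3d()].
#' @param p a [bse_params()] (scale `sigma_mm`, exponent `gamma`).
#' @return the enhancement response as a [volume3d()].
#' @export
bse_filter <- function(v, p) {
  stopifnot(inherits(v, "volume3d"), inherits(p, "bse_params"))
  h <- hessian_field(v, p$sigma_mm)
  out <- bse_from_eigen(h, p$gamma)
  volume3d(out, v$spacing, v$origin)
}

bse_from_eigen <- function(h, gamma) {
  cond <- h$l1 < 0
  out <- array(0, dim(h$l1))
  if (any(cond)) {
    l1 <- h$l1[cond]; l2 <- h$l2[cond]; l3 <- h$l3[cond]
    out[cond] <- abs(l3) * (l2 / l3)^gamma * (l1 / l2)^gamma
  }
  out
}
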