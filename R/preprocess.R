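# Gaussian and Gaussian-derivative kernels, sampled on an integer grid and
# truncated at 4 sigma. Discrete moment corrections pin the responses to
# polynomials: the smoothing kernel sums to 1, the first-derivative kernel has
# zero sum and unit first moment (exact on ramps), the second-derivative
# kernel has zero sum/first moment and second moment 2 (exact on parabolas,
# hence zero on ramps and constants).
gauss_kernel <- function(sigma, order = 0L, truncate = 4) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  u <- (-r):r
  g <- exp(-u^2 / (2 * sigma^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- u / sigma^2 * g
    k <- k - mean(k)
    return(k / sum(u * k))
  }
  if (order == 2L) {
    k <- (u^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - mean(k)
    return(k * (2 / sum(u^2 * k)))
  }
  stop("order must be 0, 1 or 2")
}

# Separable correlation of a volume's array with per-axis 1D kernels.
sepconv <- function(arr, kx, ky, kz) {
  cpp_sepconv3(arr, dim(arr), kx, ky, kz)
}

#' 3D median filter
#'
#' Replaces each voxel by the median of its `size^3` neighborhood (edge
#' replication at borders); the noise-reduction step applied to MV-CBCT
#' volumes before matching.
#'
#' @param v a [volume3d()].
#' @param size odd neighborhood edge length, default 3.
#' @return filtered [volume3d()].
#' @export
median_filter_3d <- function(v, size = 3L) {
  stopifnot(inherits(v, "volume3d"))
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    stop("median filter size must be an odd integer >= 3")
  volume3d(cpp_median3(v$data, dim(v$data), size), v$spacing, v$origin)
}

#' Laplacian-of-Gaussian response
#'
#' Sum of the three second Gaussian-derivative responses of the volume, at a
#' standard deviation given in voxel units (the CT/CBCT preprocessing uses
#' 0.7 voxels). The raw Laplacian sign convention is kept: the response is
#' negative inside bright blobs. Constants and linear ramps map to zero at
#' interior voxels.
#'
#' @param v a [volume3d()].
#' @param sigma_px Gaussian standard deviation in voxels, > 0.
#' @return the LoG response as a [volume3d()].
#' @export
log_filter <- function(v, sigma_px = 0.7) {
  stopifnot(inherits(v, "volume3d"))
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0)
    stop("`sigma_px` must be a positive scalar")
  g <- gauss_kernel(sigma_px, 0L)
  d2 <- gauss_kernel(sigma_px, 2L)
  out <- sepconv(v$data, d2, g, g) + sepconv(v$data, g, d2, g) +
    sepconv(v$data, g, g, d2)
  volume3d(out, v$spacing, v$origin)
}

#' Preprocess an MV-CBCT volume for matching
#'
#' Applies, in order, the 3x3x3 median filter for noise reduction and a
#' Laplacian-of-Gaussian edge enhancement. The default edge-enhancement mode
#' is unsharp masking, `m - LoG(m)`: the enhanced volume keeps the CT
#' intensity scale (bright tumors stay bright blobs) with sharpened edges,
#' which is what both the raw-intensity template matching and the
#' blob-structure enhancement downstream require. `edge_mode = "log"` emits
#' the raw LoG response instead, and `"none"` stops after the median filter.
#'
#' @param v an isotropic [volume3d()].
#' @param cfg config list; respected keys are `preprocess$median_size`
#'   (default 3), `preprocess$log_sigma_px` (default 0.7) and
#'   `preprocess$edge_mode` (`"sharpen"`, `"log"` or `"none"`).
#' @return preprocessed [volume3d()].
#' @export
preprocess_cbct <- function(v, cfg = list()) {
  stopifnot(inherits(v, "volume3d"))
  if (!vol_is_isotropic(v))
    stop("preprocess_cbct requires an isotropic volume; resample first")
  p <- cfg$preprocess
  size <- p$median_size %||% 3L
  sigma <- p$log_sigma_px %||% 0.7
  mode <- p$edge_mode %||% "sharpen"
  m <- median_filter_3d(v, size)
  switch(mode,
    sharpen = volume3d(m$data - log_filter(m, sigma)$data, v$spacing,
                       v$origin),
    log = log_filter(m, sigma),
    none = m,
    stop("unknown preprocess edge_mode: ", mode)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
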