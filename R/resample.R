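#' Resample a volume to isotropic spacing
#'
#' Planning CT and MV-CBCT volumes are brought to a common isotropic grid
#' before any filtering or matching: 1.0 mm for the fine pipeline, 5.0 mm for
#' the coarse rigid registration. Interpolation is either Keys tricubic
#' convolution (a = -0.5) or trilinear; out-of-range taps are edge-clamped.
#' The output grid shares the input origin and covers the input extent to
#' within one output voxel.
#'
#' @param v a [volume3d()].
#' @param target_spacing_mm positive scalar, the isotropic output spacing.
#' @param method `"tricubic"` (default) or `"trilinear"`.
#' @return a [volume3d()] with isotropic spacing.
#' @export
resample_isotropic <- function(v, target_spacing_mm,
                               method = c("tricubic", "trilinear")) {
  stopifnot(inherits(v, "volume3d"))
  method <- match.arg(method)
  t <- as.numeric(target_spacing_mm)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("`target_spacing_mm` must be a positive scalar")
  extent <- (dim(v$data) - 1) * v$spacing
  odim <- as.integer(floor(extent / t + 1e-9)) + 1L
  if (any(odim < 2L))
    stop("target spacing ", t, " mm exceeds the volume extent (",
         paste(format(extent), collapse = " x "), " mm)")
  sc <- t / v$spacing
  dat <- cpp_resample3(v$data, dim(v$data), odim, sc, c(0, 0, 0),
                       if (method == "trilinear") 0L else 1L)
  volume3d(dat, spacing = rep(t, 3), origin = v$origin)
}

# Sample `v` on an arbitrary axis-aligned output grid, optionally with the
# content rigidly translated by `shift_mm` (a point at world w in the output
# samples the input at w - shift_mm). Used by the CBCT degradation model.
resample_to_grid <- function(v, out_dim, out_spacing, out_origin,
                             shift_mm = c(0, 0, 0),
                             method = c("tricubic", "trilinear")) {
  method <- match.arg(method)
  sc <- out_spacing / v$spacing
  off <- (out_origin - shift_mm - v$origin) / v$spacing
  dat <- cpp_resample3(v$data, dim(v$data), as.integer(out_dim), sc, off,
                       if (method == "trilinear") 0L else 1L)
  volume3d(dat, spacing = out_spacing, origin = out_origin)
}
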