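#' Normalized cross-correlation of two equally shaped grids
#'
#' `C = mean((t - mean(t)) * (f - mean(f))) / (sd(t) sd(f))` with population
#' standard deviations, computed over the full (overlapped) region; the value
#' lies in `[-1, 1]` up to floating error and is invariant under positive
#' affine intensity maps of either argument.
#'
#' @param t_sub,f_sub numeric arrays of identical shape.
#' @return the correlation coefficient (scalar).
#' @export
ncc <- function(t_sub, f_sub) {
  if (inherits(t_sub, "volume3d")) t_sub <- t_sub$data
  if (inherits(f_sub, "volume3d")) f_sub <- f_sub$data
  if (!all(dim(t_sub) == dim(f_sub)) || length(t_sub) != length(f_sub))
    stop("grids must have identical shape")
  n <- length(t_sub)
  tm <- mean(t_sub); fm <- mean(f_sub)
  tsd <- sqrt(sum((t_sub - tm)^2) / n)
  fsd <- sqrt(sum((f_sub - fm)^2) / n)
  if (tsd == 0 || fsd == 0)
    stop("degenerate input: grid with zero variance")
  sum((t_sub - tm) * (f_sub - fm)) / (n * tsd * fsd)
}

#' Exhaustive translation-only rigid registration
#'
#' Slides the (smaller) MV-CBCT volume over the planning CT on the shared
#' coarse grid, evaluating the normalized cross-correlation at every integer
#' offset `0..(X-L), 0..(Y-M), 0..(Z-N)`, and returns the argmax. Ties are
#' broken by the smallest offset in lexicographic (z, y, x) order. Both
#' volumes must be isotropic at the same spacing (5 mm in the standard
#' pipeline) and the CT must be at least as large as the CBCT on every axis.
#'
#' @param ct5 planning CT [volume3d()] at coarse isotropic spacing.
#' @param cbct5 MV-CBCT [volume3d()] at the same spacing.
#' @return an object of class `translation_result`: integer `offset_vox`,
#'   `offset_mm`, NCC `score`, the grid `spacing`, and the two origins.
#' @export
register_translation <- function(ct5, cbct5) {
  stopifnot(inherits(ct5, "volume3d"), inherits(cbct5, "volume3d"))
  if (!vol_is_isotropic(ct5) || !vol_is_isotropic(cbct5) ||
      abs(ct5$spacing[1] - cbct5$spacing[1]) > 1e-6)
    stop("both volumes must be isotropic at the same spacing")
  dct <- dim(ct5$data); dcb <- dim(cbct5$data)
  if (any(dct < dcb))
    stop("MV-CBCT exceeds the planning CT on axis ",
         paste(which(dct < dcb), collapse = ","),
         "; the search ranges X-L, Y-M, Z-N must be nonnegative")
  if (stats::sd(cbct5$data) == 0)
    stop("degenerate input: MV-CBCT volume has zero variance")
  score_map <- cpp_ncc_map(ct5$data, dct, cbct5$data, dcb)
  best <- argmax_lex_zyx(score_map)
  if (best$score <= -2)
    stop("degenerate input: planning CT has zero variance at every offset")
  offset <- best$idx0
  structure(list(offset_vox = offset,
                 offset_mm = offset * ct5$spacing,
                 score = best$score,
                 spacing = ct5$spacing,
                 ct_origin = ct5$origin,
                 cbct_origin = cbct5$origin,
                 search_ranges = dct - dcb),
            class = "translation_result")
}

#' @export
print.translation_result <- function(x, ...) {
  cat(sprintf("<translation_result> offset (%s) vox = (%s) mm, NCC %.4f\n",
              paste(x$offset_vox, collapse = ", "),
              paste(format(x$offset_mm), collapse = ", "), x$score))
  invisible(x)
}

# Argmax of a 3D score map with ties broken by smallest (z, y, x)
# lexicographic order; returns the 0-based index triple and the score.
argmax_lex_zyx <- function(score_map) {
  mx <- max(score_map)
  idx <- which(score_map == mx)
  ai <- arrayInd(idx, dim(score_map))
  ord <- order(ai[, 3], ai[, 2], ai[, 1])
  list(idx0 = ai[ord[1], ] - 1L, score = mx)
}

#' Map a planning-CT GTV into MV-CBCT index space
#'
#' Applies the registration offset: the registration matches the MV-CBCT
#' window starting at CT index `offset_vox`, so a planning-CT world point `w`
#' lands at 0-based MV-CBCT voxel index
#' `round((w - ct_origin - offset_mm) / cbct_spacing)`. Volume and effective
#' diameter are carried over unchanged (they describe the planning GTV); the
#' mask is clipped to the image bounds with a warning if clipping occurs.
#'
#' @param g a [gtv_structure()] on the planning-CT grid.
#' @param tr a `translation_result` from [register_translation()].
#' @param cbct1 the fine-resolution MV-CBCT [volume3d()].
#' @return a [gtv_structure()] on the MV-CBCT grid.
#' @export
map_gtv_to_cbct <- function(g, tr, cbct1) {
  stopifnot(inherits(g, "gtv_structure"), inherits(tr, "translation_result"),
            inherits(cbct1, "volume3d"))
  if (any(abs(g$spacing - cbct1$spacing) > 1e-6))
    stop("GTV grid and MV-CBCT spacing differ; resample first")
  # world coordinate of the GTV bounding-box minimum voxel center
  w_min <- g$origin + g$bbox[1, ] * g$spacing
  idx_min <- as.integer(round((w_min - tr$ct_origin - tr$offset_mm) /
                                cbct1$spacing))
  ext <- g$bbox[2, ] - g$bbox[1, ]
  dims <- dim(cbct1$data)
  new_min <- idx_min
  new_max <- idx_min + ext
  clip_min <- pmax(new_min, 0L)
  clip_max <- pmin(new_max, dims)
  if (any(clip_min >= clip_max))
    stop("mapped GTV lies entirely outside the MV-CBCT volume")
  mask <- g$mask
  if (any(clip_min != new_min) || any(clip_max != new_max)) {
    warning("mapped GTV clipped at the MV-CBCT border")
    keep_lo <- clip_min - new_min + 1L
    keep_hi <- ext - (new_max - clip_max)
    mask <- mask[keep_lo[1]:keep_hi[1], keep_lo[2]:keep_hi[2],
                 keep_lo[3]:keep_hi[3], drop = FALSE]
    if (!any(mask)) stop("mapped GTV lies entirely outside the MV-CBCT volume")
  }
  g2 <- gtv_structure(mask, rbind(min = clip_min, max = clip_max),
                      cbct1$spacing, cbct1$origin, g$isocenter_mm)
  # volume/diameter describe the planning GTV, not the clipped copy
  g2$volume_mm3 <- g$volume_mm3
  g2$diameter_mm <- g$diameter_mm
  g2
}

#' Build the tumor search region
#'
#' The circumscribing cuboid of the mapped GTV dilated by `dilation_px`
#' voxels on every face (for a cuboid this equals `dilation_px` iterations of
#' 26-neighbor binary dilation), clipped to the image bounds.
#'
#' @param g_mapped a [gtv_structure()] in MV-CBCT index space.
#' @param cbct1 the MV-CBCT [volume3d()].
#' @param dilation_px nonnegative integer dilation, default 20.
#' @return an object of class `search_region` with a 0-based half-open `bbox`
#'   and a `provenance` record.
#' @export
build_search_region <- function(g_mapped, cbct1, dilation_px = 20L) {
  stopifnot(inherits(g_mapped, "gtv_structure"), inherits(cbct1, "volume3d"))
  dilation_px <- as.integer(dilation_px)
  if (dilation_px < 0L) stop("`dilation_px` must be nonnegative")
  dims <- dim(cbct1$data)
  lo <- pmax(g_mapped$bbox[1, ] - dilation_px, 0L)
  hi <- pmin(g_mapped$bbox[2, ] + dilation_px, dims)
  structure(list(bbox = rbind(min = lo, max = hi),
                 provenance = list(gtv_bbox = g_mapped$bbox,
                                   dilation_px = dilation_px)),
            class = "search_region")
}

#' @export
print.search_region <- function(x, ...) {
  cat(sprintf("<search_region> box [%s)-[%s) (GTV box dilated by %d px)\n",
              paste(x$bbox[1, ], collapse = ","),
              paste(x$bbox[2, ], collapse = ","),
              x$provenance$dilation_px))
  invisible(x)
}
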