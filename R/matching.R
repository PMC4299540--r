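# Crop a 0-based half-open box out of an array, clipping to bounds.
# Returns list(data, lo) where lo is the clipped 0-based minimum.
crop_box <- function(arr, lo, hi) {
  dims <- dim(arr)
  lo <- pmax(as.integer(lo), 0L)
  hi <- pmin(as.integer(hi), dims)
  if (any(lo >= hi)) stop("crop box is empty")
  list(data = arr[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                  drop = FALSE],
       lo = lo, hi = hi)
}

# Filter support radius (voxels) needed so that cropping after filtering is
# uncontaminated by the crop border.
mode_pad_vox <- function(mode, params, spacing) {
  switch(mode,
    none = 0L,
    sobel = 1L,
    bse = as.integer(ceiling(4 * params$sigma_mm / spacing[1])) + 1L,
    stop("unknown enhancement mode: ", mode)
  )
}

# Apply an enhancement mode to a volume3d.
apply_mode <- function(v, mode, params) {
  switch(mode,
    none = v,
    sobel = sobel3d(v),
    bse = bse_filter(v, params),
    stop("unknown enhancement mode: ", mode)
  )
}

#' Extract a tumor template from the planning CT
#'
#' Crops the circumscribing cuboid of the GTV from the fine-resolution
#' planning CT. For `mode = "sobel"` or `"bse"` the filter runs on a crop
#' padded by the filter support and is then trimmed back to the GTV cuboid,
#' so template voxels are identical to whole-image filtering.
#'
#' @param ct1 planning CT [volume3d()] at fine (1 mm) resolution.
#' @param g the planning [gtv_structure()].
#' @param mode `"none"`, `"sobel"` or `"bse"`.
#' @param params a [bse_params()]; required for `mode = "bse"`. If `NULL`,
#'   derived automatically as `sigma = d/4`, `gamma = 1` from the GTV.
#' @return an object of class `tumor_template` (`image`, `gtv_mask`, `mode`,
#'   `bbox`, `params`).
#' @export
extract_template <- function(ct1, g, mode = c("none", "sobel", "bse"),
                             params = NULL) {
  stopifnot(inherits(ct1, "volume3d"), inherits(g, "gtv_structure"))
  mode <- match.arg(mode)
  if (mode == "bse" && is.null(params))
    params <- bse_params(d_mm = g$diameter_mm)
  pad <- mode_pad_vox(mode, params, ct1$spacing)
  cr <- crop_box(ct1$data, g$bbox[1, ] - pad, g$bbox[2, ] + pad)
  sub <- volume3d(cr$data, ct1$spacing, ct1$origin + cr$lo * ct1$spacing)
  filt <- apply_mode(sub, mode, params)
  inner <- crop_box(filt$data, g$bbox[1, ] - cr$lo, g$bbox[2, ] - cr$lo)
  structure(list(image = inner$data, gtv_mask = g$mask, mode = mode,
                 bbox = g$bbox, params = params),
            class = "tumor_template")
}

#' Match a tumor template inside the search region
#'
#' Exhaustive normalized cross-correlation of the template over every integer
#' placement inside the search region of the (preprocessed) MV-CBCT. When the
#' template was enhancement-filtered, the region image is filtered with the
#' same mode and parameters (on a support-padded crop) before scoring. Ties
#' are broken by the smallest offset in lexicographic (z, y, x) order.
#'
#' @param region a [build_search_region()] result.
#' @param tpl a [extract_template()] result.
#' @param cbct_pre the preprocessed MV-CBCT [volume3d()].
#' @return list with `offset_vox` (0-based placement of the template within
#'   the region box), `bbox` (placed template box in MV-CBCT indices),
#'   `score`, and the filtered region dimensions.
#' @export
match_template <- function(region, tpl, cbct_pre) {
  stopifnot(inherits(region, "search_region"),
            inherits(tpl, "tumor_template"),
            inherits(cbct_pre, "volume3d"))
  rext <- region$bbox[2, ] - region$bbox[1, ]
  text <- dim(tpl$image)
  if (any(text > rext))
    stop("template (", paste(text, collapse = "x"),
         ") exceeds the search region (", paste(rext, collapse = "x"), ")")
  pad <- mode_pad_vox(tpl$mode, tpl$params, cbct_pre$spacing)
  cr <- crop_box(cbct_pre$data, region$bbox[1, ] - pad,
                 region$bbox[2, ] + pad)
  sub <- volume3d(cr$data, cbct_pre$spacing,
                  cbct_pre$origin + cr$lo * cbct_pre$spacing)
  filt <- apply_mode(sub, tpl$mode, tpl$params)
  inner <- crop_box(filt$data, region$bbox[1, ] - cr$lo,
                    region$bbox[2, ] - cr$lo)
  score_map <- tryCatch(
    cpp_ncc_map(inner$data, dim(inner$data), tpl$image, dim(tpl$image)),
    error = function(e) stop("degenerate input: ", conditionMessage(e)))
  best <- argmax_lex_zyx(score_map)
  if (best$score <= -2)
    stop("degenerate input: search region has zero variance everywhere")
  placed_min <- region$bbox[1, ] + best$idx0
  list(offset_vox = best$idx0,
       bbox = rbind(min = placed_min, max = placed_min + text),
       score = best$score)
}

#' Otsu threshold of a value set
#'
#' Histogram the values into `bins` equal-width bins over their min-max range
#' and return the bin edge maximizing the between-class variance.
#'
#' @param values numeric vector (at least 2 distinct values).
#' @param bins number of histogram bins, default 256.
#' @return the threshold (scalar); `NA` if the values are constant.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(values, breaks,
                                       rightmost.closed = TRUE), 1L), bins),
                nbins = bins)
  n <- sum(h)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  w0 <- cumsum(h)[-bins]
  m0 <- cumsum(h * mids)[-bins]
  w1 <- n - w0
  mu_t <- sum(h * mids) / n
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, bins - 1L)
  sb[valid] <- (mu_t * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  t <- which.max(sb)
  breaks[t + 1L]
}

#' Binarize the placed GTV by Otsu thresholding
#'
#' Computes the Otsu threshold from the intensities of the (preprocessed)
#' MV-CBCT voxels inside the placed GTV mask and keeps the voxels at or above
#' it. If the set is constant or the foreground would be empty, the full mask
#' is returned with a warning.
#'
#' @param cbct1 the (preprocessed) MV-CBCT [volume3d()].
#' @param placed_gtv a [gtv_structure()] in MV-CBCT index space (the GTV at
#'   its matched location).
#' @param bins histogram bins for the threshold, default 256.
#' @return list with logical array `foreground` (over the placed bounding
#'   box), the `threshold`, and `fallback` flag.
#' @export
binarize_gtv <- function(cbct1, placed_gtv, bins = 256L) {
  stopifnot(inherits(cbct1, "volume3d"), inherits(placed_gtv, "gtv_structure"))
  if (!any(placed_gtv$mask)) stop("empty placed GTV mask")
  cr <- crop_box(cbct1$data, placed_gtv$bbox[1, ], placed_gtv$bbox[2, ])
  if (!all(dim(cr$data) == dim(placed_gtv$mask)))
    stop("placed GTV extends outside the MV-CBCT volume")
  vals <- cr$data[placed_gtv$mask]
  thr <- otsu_threshold(vals, bins)
  if (is.na(thr)) {
    warning("GTV intensity set is constant; falling back to the full mask")
    return(list(foreground = placed_gtv$mask, threshold = NA_real_,
                fallback = TRUE))
  }
  fg <- placed_gtv$mask & (cr$data >= thr)
  if (!any(fg)) {
    warning("Otsu foreground empty; falling back to the full mask")
    return(list(foreground = placed_gtv$mask, threshold = thr,
                fallback = TRUE))
  }
  list(foreground = fg, threshold = thr, fallback = FALSE)
}

#' Centroid of a voxel set in world coordinates
#'
#' Arithmetic mean of the world coordinates (mm) of the member voxels.
#'
#' @param voxels either an n x 3 matrix of 0-based voxel indices, or a
#'   logical array (optionally with `bbox_min`, its 0-based offset in the
#'   reference grid).
#' @param spacing,origin geometry of the reference grid (mm).
#' @param bbox_min 0-based index offset of the array's first voxel.
#' @return numeric length-3 centroid `(x_c, y_c, z_c)` in mm.
#' @export
centroid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     bbox_min = c(0L, 0L, 0L)) {
  if (is.array(voxels) && !is.matrix(voxels)) {
    idx <- which(voxels, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty voxel set")
    voxels <- sweep(idx - 1L, 2, as.integer(bbox_min), "+")
  }
  voxels <- matrix(as.numeric(voxels), ncol = 3)
  if (nrow(voxels) == 0L) stop("empty voxel set")
  as.numeric(origin) + colMeans(voxels) * as.numeric(spacing)
}

#' Full tumor localization in one MV-CBCT fraction
#'
#' Composes the pipeline stages: map the planning GTV through the coarse
#' registration, build the dilated search region, extract the (optionally
#' enhancement-filtered) planning-CT template, match it exhaustively by
#' normalized cross-correlation, place the GTV at the matched location,
#' binarize it by Otsu thresholding on the preprocessed MV-CBCT, and report
#' the centroid of the binarized region as the estimated tumor location. The
#' result is deterministic for fixed inputs and configuration.
#'
#' @param ct1 planning CT [volume3d()] at fine resolution (raw intensities).
#' @param cbct1 MV-CBCT [volume3d()] at fine resolution (raw intensities).
#' @param g planning [gtv_structure()].
#' @param tr `translation_result` from [register_translation()].
#' @param cfg config list (see [default_config()]); `cfg$enhance$mode`
#'   selects the template mode.
#' @param cbct_pre optional precomputed [preprocess_cbct()] output (reused
#'   across modes by the batch driver).
#' @return an object of class `localization_result`: estimated
#'   `centroid_mm`, matched `offset_vox` and placed `bbox`, NCC `score`,
#'   Otsu `threshold`, mode, and accumulated warnings.
#' @export
localize <- function(ct1, cbct1, g, tr, cfg = default_config(),
                     cbct_pre = NULL) {
  stopifnot(inherits(ct1, "volume3d"), inherits(cbct1, "volume3d"))
  mode <- cfg$enhance$mode %||% "bse"
  warnings <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (is.null(cbct_pre)) cbct_pre <- preprocess_cbct(cbct1, cfg)
  params <- if (mode == "bse") {
    sigma <- cfg$enhance$sigma_mm
    bse_params(sigma_mm = sigma, gamma = cfg$enhance$gamma %||% 1,
               d_mm = g$diameter_mm)
  } else NULL
  g_m <- wh(map_gtv_to_cbct(g, tr, cbct1))
  sr <- build_search_region(g_m, cbct1,
                            cfg$registration$dilation_px %||% 20L)
  tpl <- extract_template(ct1, g, mode, params)
  mt <- match_template(sr, tpl, cbct_pre)
  placed <- gtv_structure(tpl$gtv_mask, mt$bbox, cbct1$spacing,
                          cbct1$origin, g$isocenter_mm)
  bin <- wh(binarize_gtv(cbct_pre, placed, cfg$otsu$bins %||% 256L))
  cen <- centroid(bin$foreground, cbct1$spacing, cbct1$origin,
                  bbox_min = mt$bbox[1, ])
  structure(list(centroid_mm = cen, offset_vox = mt$offset_vox,
                 bbox = mt$bbox, score = mt$score,
                 threshold = bin$threshold, mode = mode,
                 search_region = sr, warnings = warnings),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "<localization_result> mode %s: centroid (%s) mm, NCC %.4f\n",
    x$mode, paste(sprintf("%.2f", x$centroid_mm), collapse = ", "), x$score))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
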