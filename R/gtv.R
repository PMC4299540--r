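#' Gross tumor volume (GTV) structure
#'
#' A binary tumor delineation aligned to a reference [volume3d()] grid. The
#' mask is stored cropped to its circumscribing cuboid; `bbox` gives that
#' cuboid as 0-based half-open voxel index ranges `[min, max)` per axis in
#' the reference grid. The structure carries its volume `V` (mm^3), the
#' effective diameter `d = 2 (3V / 4 pi)^(1/3)` (mm) used to scale the blob
#' enhancement filter, and optionally the plan isocenter (mm).
#'
#' @param mask logical/numeric array covering exactly the bounding cuboid;
#'   must contain at least one TRUE voxel on its faces (i.e. be cropped).
#' @param bbox 2x3 matrix, rows `min` and `max` (0-based, half-open).
#' @param spacing,origin geometry of the reference grid (mm).
#' @param isocenter_mm optional world coordinate of the plan isocenter.
#' @return an object of class `gtv_structure`.
#' @export
gtv_structure <- function(mask, bbox, spacing, origin, isocenter_mm = NULL) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("empty GTV structure: mask has no voxels")
  bbox <- rbind(min = as.integer(bbox[1, ]), max = as.integer(bbox[2, ]))
  if (!all(dim(mask) == bbox[2, ] - bbox[1, ]))
    stop("mask dimensions do not match the bounding cuboid")
  vox_mm3 <- prod(spacing)
  V <- sum(mask) * vox_mm3
  structure(list(mask = mask, bbox = bbox, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), volume_mm3 = V,
                 diameter_mm = effective_diameter(V),
                 isocenter_mm = if (!is.null(isocenter_mm))
                   as.numeric(isocenter_mm)),
            class = "gtv_structure")
}

#' @export
print.gtv_structure <- function(x, ...) {
  cat(sprintf(
    "<gtv_structure> %d voxels, V = %.1f mm^3, d = %.2f mm, box [%s)-[%s)\n",
    sum(x$mask), x$volume_mm3, x$diameter_mm,
    paste(x$bbox[1, ], collapse = ","), paste(x$bbox[2, ], collapse = ",")))
  invisible(x)
}

# Build a gtv_structure from a full-grid logical mask.
gtv_from_full_mask <- function(mask, spacing, origin, isocenter_mm = NULL) {
  if (!any(mask)) stop("empty GTV structure: mask has no voxels")
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  bbox <- rbind(min = lo - 1L, max = hi)
  cropped <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  gtv_structure(cropped, bbox, spacing, origin, isocenter_mm)
}

#' Centroid of a GTV mask in world coordinates (mm)
#' @param g a [gtv_structure()].
#' @return numeric length-3 world coordinate.
#' @export
gtv_centroid <- function(g) {
  idx <- which(g$mask, arr.ind = TRUE)
  idx0 <- sweep(idx - 1L, 2, g$bbox[1, ], "+")
  g$origin + colMeans(idx0) * g$spacing
}

#' Convert per-slice closed polygon contours to a GTV mask
#'
#' Voxelizes axial contours (the JSON stand-in for a DICOM-RT structure set)
#' onto the grid of `target`. A voxel belongs to the GTV iff its center lies
#' inside the polygon(s) of its slice under the even-odd rule; several
#' polygons on one slice combine by exclusive-or, so nested loops cut holes.
#'
#' @param contours either a path to a contour JSON file or a list with
#'   elements `slices` (each `list(z_mm=, points_mm=)` where `points_mm` is an
#'   n x 2 matrix of x,y vertices in mm) and optionally `isocenter_mm`.
#' @param target the reference [volume3d()] defining the voxel grid.
#' @return a [gtv_structure()].
#' @export
contours_to_mask <- function(contours, target) {
  stopifnot(inherits(target, "volume3d"))
  if (is.character(contours)) contours <- read_contours_json(contours)
  slices <- contours$slices
  if (is.null(slices) || length(slices) == 0L)
    stop("contour set contains no slices")
  dims <- dim(target$data)
  zw <- axis_world(target, 3)
  xw <- axis_world(target, 1)
  yw <- axis_world(target, 2)
  mask <- array(FALSE, dim = dims)
  for (sl in slices) {
    k <- which(abs(zw - sl$z_mm) <= target$spacing[3] / 2 + 1e-9)
    if (length(k) == 0L) next
    k <- k[which.min(abs(zw[k] - sl$z_mm))]
    pts <- sl$points_mm
    if (is.list(pts) && !is.matrix(pts)) pts <- do.call(rbind, pts)
    pts <- matrix(as.numeric(pts), ncol = 2)
    if (nrow(pts) < 3L) next
    xi <- which(xw >= min(pts[, 1]) - target$spacing[1] &
                xw <= max(pts[, 1]) + target$spacing[1])
    yi <- which(yw >= min(pts[, 2]) - target$spacing[2] &
                yw <= max(pts[, 2]) + target$spacing[2])
    if (length(xi) == 0L || length(yi) == 0L) next
    gx <- rep(xw[xi], times = length(yi))
    gy <- rep(yw[yi], each = length(xi))
    inside <- pracma::inpolygon(gx, gy, pts[, 1], pts[, 2],
                                boundary = FALSE)
    sl_mask <- matrix(inside, nrow = length(xi))
    mask[xi, yi, k] <- xor(mask[xi, yi, k], sl_mask)
  }
  if (!any(mask))
    stop("empty GTV structure: no contour encloses any voxel center ",
         "of the target grid")
  gtv_from_full_mask(mask, target$spacing, target$origin,
                     contours$isocenter_mm)
}

#' Read the JSON contour dialect
#'
#' Format: `{"slices": [{"z_mm": z, "points_mm": [[x, y], ...]}, ...],
#' "isocenter_mm": [x, y, z]}`.
#'
#' @param path path to a JSON file.
#' @return a contour list usable by [contours_to_mask()].
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$slices)) stop("contour JSON lacks a 'slices' element")
  slices <- obj$slices
  if (is.data.frame(slices)) {
    slices <- lapply(seq_len(nrow(slices)), function(i)
      list(z_mm = slices$z_mm[i], points_mm = slices$points_mm[[i]]))
  }
  list(slices = slices, isocenter_mm = obj$isocenter_mm)
}

#' Write contours in the JSON dialect
#' @param contours a contour list (see [contours_to_mask()]).
#' @param path output path.
#' @export
write_contours_json <- function(contours, path) {
  jsonlite::write_json(contours, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
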