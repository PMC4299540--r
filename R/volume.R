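#' 3D scalar volume with geometry metadata
#'
#' The basic image container of the package: a 3D numeric array together with
#' per-axis voxel spacing (mm) and the world coordinate of the center of voxel
#' `(0,0,0)` (mm). The axis convention is fixed: x runs left to right, y
#' anterior to posterior, z inferior to superior, and the array is stored with
#' x as the fastest-varying index. Only axis-aligned volumes are supported.
#'
#' @param data numeric 3D array (HU or filter-response units).
#' @param spacing numeric length-3, per-axis voxel size in mm, all > 0.
#' @param origin numeric length-3, world coordinate (mm) of voxel (0,0,0).
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 5), collapse = ", "),
              paste(format(x$origin, digits = 5), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

vol_is_isotropic <- function(v, tol = 1e-6) {
  diff(range(v$spacing)) <= tol * mean(v$spacing)
}

#' World coordinates of voxel centers along one axis
#' @noRd
axis_world <- function(v, axis) {
  v$origin[axis] + (seq_len(dim(v$data)[axis]) - 1) * v$spacing[axis]
}

# ---------------------------------------------------------------------------
# File I/O: NIfTI through RNifti, MetaImage (.mha/.mhd) natively.

infer_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.mh[ad]$", lp)) return("metaimage")
  stop("cannot infer volume format from extension of '", path,
       "' (expected .nii, .nii.gz, .mha or .mhd)")
}

#' Read a volume from NIfTI or MetaImage
#'
#' Spacing and origin are taken from the file header; voxel values are
#' preserved bit-exactly for integer-typed inputs. Only axis-aligned images
#' (no rotation in the orientation matrix) are accepted.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param format `"nifti"`, `"metaimage"` or `NULL` to infer from extension.
#' @return a [volume3d()].
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format)) format <- infer_format(path)
  switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage(path),
    stop("unknown format: ", format)
  )
}

#' Write a volume to NIfTI or MetaImage
#'
#' Integer-valued volumes within 16-bit range are stored as `int16`
#' (matching the 12-bit depth of CT/CBCT acquisitions); everything else as
#' `float64`.
#'
#' @param v a [volume3d()].
#' @param path output path; extension selects the format unless `format` given.
#' @param format `"nifti"`, `"metaimage"` or `NULL`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = NULL) {
  stopifnot(inherits(v, "volume3d"))
  if (is.null(format)) format <- infer_format(path)
  switch(format,
    nifti = write_nifti_volume(v, path),
    metaimage = write_metaimage(v, path),
    stop("unknown format: ", format)
  )
  invisible(path)
}

is_integral <- function(x) {
  all(x == round(x)) && max(abs(x)) <= 32767
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI image in ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header of '", path, "' is missing a valid pixdim (spacing)")
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4, 4))) {
    rot <- xf[1:3, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
      stop("NIfTI image '", path, "' is not axis-aligned; ",
           "rotated orientation matrices are not supported")
    if (all(diag(rot) > 0)) org <- xf[1:3, 4]
  }
  dat <- array(as.numeric(arr), dim = dim(arr))
  volume3d(dat, spacing = as.numeric(sp), origin = as.numeric(org))
}

write_nifti_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- v$spacing
  aff[1:3, 4] <- v$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  dt <- if (is_integral(v$data)) "int16" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
}

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_UINT = "integer",
                     MET_FLOAT = "double", MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2,
                     MET_USHORT = 2, MET_INT = 4, MET_UINT = 4,
                     MET_FLOAT = 4, MET_DOUBLE = 8)
metaimage_signed <- c(MET_UCHAR = FALSE, MET_CHAR = TRUE, MET_SHORT = TRUE,
                      MET_USHORT = FALSE, MET_INT = TRUE, MET_UINT = FALSE,
                      MET_FLOAT = TRUE, MET_DOUBLE = TRUE)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("MetaImage header of '", path,
           "' ended before ElementDataFile; file is truncated or not MetaImage")
    m <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(m) != 3L) stop("malformed MetaImage header line in '", path,
                              "': ", line)
    hdr[[m[2]]] <- m[3]
    if (m[2] == "ElementDataFile") break
  }
  for (key in c("DimSize", "ElementSpacing", "ElementType"))
    if (is.null(hdr[[key]]))
      stop("MetaImage header of '", path, "' is missing required field ", key)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("expected NDims = 3 in '", path, "'")
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  if (!type %in% names(metaimage_types))
    stop("unsupported MetaImage ElementType ", type, " in '", path, "'")
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      tolower(hdr$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage files are not supported ('", path, "')")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, what = metaimage_types[[type]], n = n + 1L,
                   size = metaimage_sizes[[type]],
                   signed = metaimage_signed[[type]], endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath))
      stop("MetaImage data file not found: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, what = metaimage_types[[type]], n = n + 1L,
                   size = metaimage_sizes[[type]],
                   signed = metaimage_signed[[type]], endian = "little")
  }
  if (length(raw) < n)
    stop("MetaImage file '", path, "' is truncated: expected ", n,
         " voxels, found ", length(raw))
  volume3d(array(as.numeric(raw[seq_len(n)]), dim = dims),
           spacing = sp, origin = org)
}

write_metaimage <- function(v, path) {
  dims <- dim(v$data)
  integral <- is_integral(v$data)
  type <- if (integral) "MET_SHORT" else "MET_DOUBLE"
  ext <- tolower(tools::file_ext(path))
  local_data <- !identical(ext, "mhd")
  datafile <- if (local_data) "LOCAL" else
    paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(sprintf("%.15g", v$origin),
                                   collapse = " ")),
           paste("ElementSpacing =", paste(sprintf("%.15g", v$spacing),
                                           collapse = " ")),
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  payload <- if (integral) as.integer(v$data) else as.numeric(v$data)
  if (local_data) {
    writeBin(payload, con, size = if (integral) 2L else 8L,
             endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(payload, rcon, size = if (integral) 2L else 8L,
             endian = "little")
    close(rcon)
  }
  invisible(path)
}
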