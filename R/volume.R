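#' 3D scalar volume with voxel geometry
#'
#' The universal container of the pipeline: a 3D intensity array plus the
#' voxel spacing and world origin. The internal convention is fixed: voxel
#' indices are 0-based, and the world coordinate of voxel `(i,j,k)` is
#' `origin + c(i,j,k) * spacing` (voxel-center convention). Axis order is
#' the array's native `[x, y, z]` order; all readers map their on-disk
#' layout into this one convention.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Numeric 3-vector, voxel size per axis (world units per
#'   voxel, all finite and > 0).
#' @param origin Numeric 3-vector, world coordinate of the center of voxel
#'   `(0,0,0)`.
#' @return An object of class `swd_volume`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 finite positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("origin must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "swd_volume")
}

#' @export
print.swd_volume <- function(x, ...) {
  cat(sprintf("<swd_volume %s  spacing [%s]  origin [%s]  range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "swd_volume")

#' World coordinates of every voxel center
#' @param v A volume.
#' @return List of three arrays (x, y, z world coordinates).
#' @keywords internal
voxel_world_coords <- function(v) {
  d <- dim(v$data)
  ix <- (seq_len(d[1]) - 1) * v$spacing[1] + v$origin[1]
  iy <- (seq_len(d[2]) - 1) * v$spacing[2] + v$origin[2]
  iz <- (seq_len(d[3]) - 1) * v$spacing[3] + v$origin[3]
  list(x = array(rep(ix, times = d[2] * d[3]), d),
       y = array(rep(rep(iy, each = d[1]), times = d[3]), d),
       z = array(rep(iz, each = d[1] * d[2]), d))
}

#' Trilinear interpolation at fractional 0-based voxel coordinates
#'
#' Core sampler shared by spherical sampling, resampling, and warping.
#' Coordinates outside the grid return `fill`.
#'
#' @param data 3D array.
#' @param xi,yi,zi Numeric vectors of fractional voxel indices (0-based).
#' @param fill Value for out-of-grid queries.
#' @return Numeric vector of interpolated values.
#' @keywords internal
interp_trilinear <- function(data, xi, yi, zi, fill = 0) {
  d <- dim(data)
  eps <- 1e-9  # tolerate rounding at the grid boundary
  inside <- xi >= -eps & xi <= d[1] - 1 + eps & yi >= -eps &
    yi <= d[2] - 1 + eps & zi >= -eps & zi <= d[3] - 1 + eps
  out <- rep(fill, length(xi))
  if (!any(inside)) return(out)
  x <- pmin(pmax(xi[inside], 0), d[1] - 1)
  y <- pmin(pmax(yi[inside], 0), d[2] - 1)
  z <- pmin(pmax(zi[inside], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(z), d[3] - 2); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # linear index of corner (1-based)
  i000 <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- data[i000];           v100 <- data[i000 + sx]
  v010 <- data[i000 + sy];      v110 <- data[i000 + sx + sy]
  v001 <- data[i000 + sz];      v101 <- data[i000 + sx + sz]
  v011 <- data[i000 + sy + sz]; v111 <- data[i000 + sx + sy + sz]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Sample a volume at world coordinates
#' @keywords internal
sample_world <- function(v, wx, wy, wz, fill = 0) {
  interp_trilinear(v$data,
                   (wx - v$origin[1]) / v$spacing[1],
                   (wy - v$origin[2]) / v$spacing[2],
                   (wz - v$origin[3]) / v$spacing[3],
                   fill = fill)
}

finalize_loaded <- function(data, spacing, origin, na_action, path) {
  storage.mode(data) <- "double"
  bad <- !is.finite(data)
  if (any(bad)) {
    if (identical(na_action, "zero")) {
      data[bad] <- 0
      swd_log(sum(bad), " non-finite voxels zero-filled in ", path)
    } else {
      stopf("volume '%s' contains %d non-finite voxels (use na_action='zero' to zero-fill)",
            path, sum(bad))
    }
  }
  volume(data, spacing, origin)
}

#' Read a volume from disk
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`), a directory of
#' lexicographically sorted TIFF slices with a `meta.json` sidecar
#' (`{"spacing": [x,y,z], "origin": [x,y,z]}`, optional `"scale"`/`"offset"`
#' written by [write_volume()]), or a `.raw` file with a JSON sidecar
#' (`{"shape", "dtype", "spacing", "origin", "byte_order"}`). Integer data
#' are promoted to double; non-finite voxels are rejected by default.
#'
#' @param path File (or, for TIFF stacks, directory) path.
#' @param na_action `"error"` (default) or `"zero"` for NaN/Inf voxels.
#' @return A [volume()].
#' @export
read_volume <- function(path, na_action = c("error", "zero")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (dir.exists(path)) return(read_tiff_stack(path, na_action))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return(read_nifti_volume(path, na_action))
  if (grepl("\\.raw$", lower)) return(read_raw_volume(path, na_action))
  stopf("unsupported volume format: %s", path)
}

read_nifti_volume <- function(path, na_action) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L) stopf("'%s' is not a 3D volume", path)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  finalize_loaded(arr, spacing, origin, na_action, path)
}

read_raw_volume <- function(path, na_action) {
  sidecar <- paste0(sub("\\.raw$", "", path, ignore.case = TRUE), ".json")
  if (!file.exists(sidecar)) stopf("raw volume '%s' needs sidecar '%s'", path, sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("shape", "dtype", "spacing", "origin")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("raw sidecar missing metadata: %s", paste(miss, collapse = ", "))
  shape <- as.integer(meta$shape)
  endian <- switch(meta$byte_order %||% "little", little = "little", big = "big",
                   stopf("unknown byte_order '%s'", meta$byte_order))
  spec <- switch(meta$dtype,
                 float64 = list(what = "double", size = 8),
                 float32 = list(what = "double", size = 4),
                 int32 = list(what = "integer", size = 4),
                 int16 = list(what = "integer", size = 2),
                 uint8 = list(what = "integer", size = 1, signed = FALSE),
                 stopf("unsupported raw dtype '%s'", meta$dtype))
  n <- prod(shape)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed %||% TRUE, endian = endian)
  if (length(vals) != n) stopf("raw file '%s' truncated: expected %d values", path, n)
  finalize_loaded(array(as.numeric(vals), shape), meta$spacing, meta$origin,
                  na_action, path)
}

read_tiff_stack <- function(path, na_action) {
  slices <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                            full.names = TRUE))
  if (!length(slices)) stopf("no TIFF slices in %s", path)
  sidecar <- file.path(path, "meta.json")
  if (!file.exists(sidecar))
    stopf("TIFF stack '%s' needs a meta.json sidecar with spacing", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$spacing)) stopf("TIFF sidecar missing spacing")
  planes <- lapply(slices, tiff::readTIFF)
  d2 <- dim(planes[[1]])
  arr <- array(0, c(d2[2], d2[1], length(planes)))  # slice rows = y, cols = x
  for (k in seq_along(planes)) arr[, , k] <- t(planes[[k]])
  scale <- meta$scale %||% 1
  offset <- meta$offset %||% 0
  arr <- arr * scale + offset
  finalize_loaded(arr, meta$spacing, meta$origin %||% c(0, 0, 0), na_action, path)
}

#' Write a volume to disk
#'
#' Format chosen by extension/target: `.nii`/`.nii.gz` (lossless float64),
#' `.raw` (lossless float64 + JSON sidecar), or a directory path for a
#' TIFF stack (32-bit samples rescaled to `[0,1]`; the scale/offset are
#' recorded in the sidecar, so the round trip is exact to ~1e-9 of the
#' intensity range).
#'
#' @param v A [volume()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    m <- diag(c(v$spacing, 1)); m[1:3, 4] <- v$origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.raw$", lower)) {
    con <- file(path, "wb")
    writeBin(as.vector(v$data), con, size = 8, endian = "little")
    close(con)
    sidecar <- paste0(sub("\\.raw$", "", path, ignore.case = TRUE), ".json")
    jsonlite::write_json(list(shape = dim(v$data), dtype = "float64",
                              spacing = v$spacing, origin = v$origin,
                              byte_order = "little"),
                         sidecar, auto_unbox = FALSE, digits = NA)
  } else if (!grepl("\\.[a-z0-9]+$", basename(lower))) {
    write_tiff_stack(v, path)
  } else {
    stopf("unsupported output format: %s", path)
  }
  invisible(path)
}

write_tiff_stack <- function(v, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v$data)
  lo <- min(v$data); hi <- max(v$data)
  scale <- if (hi > lo) hi - lo else 1
  nd <- max(nchar(as.character(d[3])), 4)
  for (k in seq_len(d[3])) {
    plane <- t((v$data[, , k] - lo) / scale)  # rows = y, cols = x
    tiff::writeTIFF(plane, file.path(path, sprintf("slice_%0*d.tif", nd, k)),
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(list(spacing = v$spacing, origin = v$origin,
                            scale = scale, offset = lo),
                       file.path(path, "meta.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear resampling onto an isotropic grid with the same origin; the
#' world extent is preserved to within one voxel. The spherical wave basis
#' assumes an isotropic metric, so anisotropic inputs pass through here
#' before decomposition.
#'
#' @param v A [volume()].
#' @param target_spacing Positive scalar, the new voxel size.
#' @return A [volume()] with `spacing = rep(target_spacing, 3)`.
#' @export
resample_isotropic <- function(v, target_spacing) {
  stopifnot(is_volume(v), target_spacing > 0)
  if (all(abs(v$spacing - target_spacing) < 1e-12 * target_spacing)) return(v)
  d <- dim(v$data)
  extent <- (d - 1) * v$spacing
  nd <- pmax(1L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  ix <- (seq_len(nd[1]) - 1) * target_spacing / v$spacing[1]
  iy <- (seq_len(nd[2]) - 1) * target_spacing / v$spacing[2]
  iz <- (seq_len(nd[3]) - 1) * target_spacing / v$spacing[3]
  xi <- rep(ix, times = nd[2] * nd[3])
  yi <- rep(rep(iy, each = nd[1]), times = nd[3])
  zi <- rep(iz, each = nd[1] * nd[2])
  out <- interp_trilinear(v$data, xi, yi, zi)
  swd_log(sprintf("resampled %s @ [%s] -> %s @ %.4g",
                  paste(d, collapse = "x"),
                  paste(signif(v$spacing, 4), collapse = ","),
                  paste(nd, collapse = "x"), target_spacing))
  volume(array(out, nd), rep(target_spacing, 3), v$origin)
}
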