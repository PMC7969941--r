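#' CT volume container
#'
#' Bundles a 3D grid of Hounsfield-unit (HU) voxel values with its physical
#' voxel spacing and origin. Voxels are stored in `(z, y, x)` order so that
#' `vol$voxels[z, , ]` is an axial slice with rows along y and columns along x.
#'
#' @param voxels 3D numeric array in `(z, y, x)` order.
#' @param spacing numeric length-3 `(dx, dy, dz)` in mm; all components > 0.
#'   `dz` is the inter-slice distance used by the adjacent-contour threshold.
#' @param origin numeric length-3 `(ox, oy, oz)` in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("voxels must be a non-empty 3D array in (z, y, x) order")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (dx, dy, dz) in mm; got: ",
         paste(spacing, collapse = ", "))
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d slices of %d x %d (y x x), spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask on a CT grid
#'
#' @param voxels 3D array of 0/1 values, `(z, y, x)` order.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm (same grid as the source
#'   volume).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("mask voxels must be a 3D array")
  if (!all(voxels %in% c(0, 1)))
    stop("mask voxels must be 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values")
  structure(list(voxels = voxels, spacing = spacing), class = "binary_mask")
}

#' Seed point (0-based voxel indices)
#'
#' The single user interaction of the pipeline: one voxel inside the liver.
#' Indices are 0-based on the CLI and throughout the public interface.
#'
#' @param x,y column/row pixel indices (0-based).
#' @param z slice index (0-based).
#' @return An object of class `seed_point`.
#' @export
seed_point <- function(x, y, z) {
  s <- c(x = as.integer(x), y = as.integer(y), z = as.integer(z))
  if (any(is.na(s)) || any(s < 0)) stop("seed indices must be non-negative integers")
  structure(as.list(s), class = "seed_point")
}

# ---- MetaImage (.mhd + .raw) ------------------------------------------------

.met_types <- data.frame(
  met = c("MET_UCHAR", "MET_CHAR", "MET_USHORT", "MET_SHORT", "MET_UINT",
          "MET_INT", "MET_FLOAT", "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer", "integer",
           "integer", "double", "double"),
  size = c(1L, 1L, 2L, 2L, 4L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

read_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) if (length(x) > 1) trimws(x[2]) else "", "")
  stats::setNames(as.list(vals), keys)
}

read_metaimage <- function(path) {
  h <- read_mhd_header(path)
  need <- function(key) {
    if (is.null(h[[key]]) || !nzchar(h[[key]]))
      stop("MetaImage header ", path, " is missing required field '", key, "'")
    h[[key]]
  }
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D MetaImage volumes are supported")
  sp_key <- if (!is.null(h[["ElementSpacing"]])) "ElementSpacing" else "ElementSize"
  if (is.null(h[[sp_key]]))
    stop("MetaImage header ", path,
         " is missing required field 'ElementSpacing'")
  spacing <- as.numeric(strsplit(h[[sp_key]], "\\s+")[[1]])
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("MetaImage field 'ElementSpacing' must hold 3 positive values; got '",
         h[[sp_key]], "'")
  origin <- if (!is.null(h[["Offset"]]))
    as.numeric(strsplit(h[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  ti <- match(need("ElementType"), .met_types$met)
  if (is.na(ti)) stop("unsupported MetaImage ElementType: ", h[["ElementType"]])
  msb <- isTRUE(tolower(h[["BinaryDataByteOrderMSB"]]) == "true") ||
    isTRUE(tolower(h[["ElementByteOrderMSB"]]) == "true")
  raw_file <- need("ElementDataFile")
  if (raw_file == "LOCAL") stop("inline (LOCAL) MetaImage data is not supported")
  raw_path <- file.path(dirname(path), raw_file)
  if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  data <- readBin(con, what = .met_types$what[ti], n = n,
                  size = .met_types$size[ti], signed = .met_types$signed[ti],
                  endian = if (msb) "big" else "little")
  if (length(data) != n)
    stop("MetaImage data file ", raw_path, " is truncated: expected ",
         n, " values, read ", length(data))
  # raw order is x-fastest; reorder to internal (z, y, x)
  vox <- aperm(array(data, dim = dims), c(3, 2, 1))
  ct_volume(vox, spacing = spacing, origin = origin)
}

write_metaimage <- function(vol, path, element_type = "MET_FLOAT") {
  ti <- match(element_type, .met_types$met)
  if (is.na(ti)) stop("unsupported ElementType: ", element_type)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(vol$voxels)  # (z, y, x)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("Offset = %.10g %.10g %.10g", vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, path)
  data <- aperm(vol$voxels, c(3, 2, 1))  # back to x-fastest
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (.met_types$what[ti] == "integer") {
    writeBin(as.integer(round(data)), con, size = .met_types$size[ti],
             endian = "little")
  } else {
    writeBin(as.double(data), con, size = .met_types$size[ti], endian = "little")
  }
  invisible(path)
}

# ---- NIfTI ------------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("only 3D NIfTI volumes are supported: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI file ", path, " has invalid 'pixdim' spacing: ",
         paste(sp, collapse = ", "))
  h <- RNifti::niftiHeader(img)
  origin <- c(h$qoffset_x, h$qoffset_y, h$qoffset_z)
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = sp, origin = origin)
}

write_nifti_volume <- function(vol, path) {
  arr <- aperm(vol$voxels, c(3, 2, 1))  # NIfTI stores (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a CT volume from MetaImage or NIfTI
#'
#' Format is chosen by extension: `.mhd` for MetaImage (header + `.raw`),
#' `.nii`/`.nii.gz` for NIfTI. HU values are passed through untouched; spacing
#' metadata is mandatory and validated.
#'
#' @param path path to a `.mhd` header or NIfTI file.
#' @return A [ct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  if (is_nifti_path(path)) read_nifti_volume(path)
  else if (grepl("\\.mhd$", path, ignore.case = TRUE)) read_metaimage(path)
  else stop("unrecognised volume format (expected .mhd or .nii/.nii.gz): ", path)
}

#' Write a CT volume to MetaImage or NIfTI
#'
#' @param vol a [ct_volume].
#' @param path output path (`.mhd` or `.nii`/`.nii.gz`).
#' @param element_type MetaImage element type for `.mhd` output
#'   (default `MET_SHORT`, adequate for HU).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, element_type = "MET_SHORT") {
  if (is_nifti_path(path)) write_nifti_volume(vol, path)
  else write_metaimage(vol, path, element_type = element_type)
}

#' Read / write binary masks
#'
#' Masks are exchanged as 0/1 volumes (8-bit in MetaImage) on the same grid
#' and spacing as their source CT volume.
#'
#' @param path mask file (`.mhd` or `.nii`/`.nii.gz`).
#' @return [read_mask]: a [binary_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vox <- v$voxels
  if (!all(vox %in% c(0, 1))) vox <- (vox != 0) + 0
  binary_mask(vox, spacing = v$spacing)
}

#' @rdname read_mask
#' @param mask a [binary_mask].
#' @export
write_mask <- function(mask, path) {
  vol <- ct_volume(mask$voxels, spacing = mask$spacing)
  write_volume(vol, path, element_type = "MET_UCHAR")
}

#' Apply the fixed liver display window
#'
#' Clips HU to `[level - width/2, level + width/2]` and maps the result
#' linearly onto `[0, 255]`. The defaults (W = 150, L = 80 HU) are the typical
#' liver display preset; all downstream feature extraction and boundary costs
#' operate on these windowed intensities. Values are kept as reals (no
#' quantisation to integers).
#'
#' @param vol a [ct_volume].
#' @param width window width in HU (> 0).
#' @param level window level (centre) in HU.
#' @return A `windowed_volume`: list with `intensities` (3D array in
#'   `[0, 255]`), `window_width`, `window_level`, `spacing`.
#' @export
apply_window <- function(vol, width = 150, level = 80) {
  if (!is.finite(width) || width <= 0) stop("window width must be > 0")
  lo <- level - width / 2
  x <- pmin(pmax(vol$voxels, lo), level + width / 2)
  structure(
    list(intensities = (x - lo) * (255 / width),
         window_width = width, window_level = level, spacing = vol$spacing),
    class = "windowed_volume"
  )
}

#' Validate a seed point against a volume
#'
#' The seed must lie strictly inside the volume and keep at least half a
#' feature patch (5 px for the default 11-px patch) of margin from the slice
#' borders, so the model patch fits entirely inside its slice.
#'
#' @param seed a [seed_point] (0-based indices).
#' @param vol a [ct_volume] (or anything with `$voxels`).
#' @param margin in-plane margin in pixels (default 5 = half an 11-px patch).
#' @return `seed`, unchanged, if valid; otherwise an error listing the valid
#'   ranges.
#' @export
validate_seed <- function(seed, vol, margin = 5L) {
  d <- dim(vol$voxels)  # (nz, ny, nx)
  ok_x <- seed$x >= margin && seed$x <= d[3] - 1L - margin
  ok_y <- seed$y >= margin && seed$y <= d[2] - 1L - margin
  ok_z <- seed$z >= 0L && seed$z <= d[1] - 1L
  if (!(ok_x && ok_y && ok_z))
    stop(sprintf(
      "seed (%d, %d, %d) out of range: x in [%d, %d], y in [%d, %d], z in [%d, %d]",
      seed$x, seed$y, seed$z, margin, d[3] - 1L - margin,
      margin, d[2] - 1L - margin, 0L, d[1] - 1L))
  seed
}
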