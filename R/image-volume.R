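#' Grayscale image volume
#'
#' The shared raster container for all segmentation methods: a 2D (`H x W`) or
#' 3D (`H x W x D`, i.e. row, column, slice) array of finite real intensities
#' plus physical voxel spacing in millimetres and pass-through origin/direction
#' metadata. Indices are 1-based, R array order, throughout the package.
#'
#' @param data Numeric array with 2 or 3 dimensions, all values finite.
#' @param spacing Positive numeric vector, one entry per axis (mm). Defaults
#'   to unit spacing.
#' @param origin,direction Optional metadata carried through unchanged.
#'
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing`, `origin`, `direction`.
#' @examples
#' img <- image_volume(matrix(1:12, 3, 4), spacing = c(1.5, 1.5))
#' dim(img$data)
#' @export
image_volume <- function(data, spacing = NULL, origin = NULL, direction = NULL) {
  data <- as.array(data)
  if (is.null(dim(data))) dim(data) <- length(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L))
    stop("image_volume: data must have 2 or 3 axes, got ", nd, call. = FALSE)
  if (any(dim(data) < 1L))
    stop("image_volume: every axis length must be >= 1", call. = FALSE)
  data <- array(as.double(data), dim(data))   # drop foreign attributes
  if (!all(is.finite(data)))
    stop("image_volume: all intensities must be finite", call. = FALSE)
  if (is.null(spacing)) spacing <- rep(1, nd)
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be strictly positive, one value per axis",
         call. = FALSE)
  structure(list(data = data, spacing = spacing,
                 origin = origin, direction = direction),
            class = "image_volume")
}

#' Binary segmentation mask
#'
#' A logical array congruent with an [image_volume()], used both as
#' segmentation input (markers, ground truth) and output.
#'
#' @param data Logical (or 0/1 numeric) array with 2 or 3 dimensions.
#' @param spacing,origin,direction As in [image_volume()].
#' @return An object of class `binary_mask` (fields as `image_volume`).
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
#' sum(m$data)
#' @export
binary_mask <- function(data, spacing = NULL, origin = NULL, direction = NULL) {
  data <- as.array(data)
  if (is.null(dim(data))) dim(data) <- length(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L))
    stop("binary_mask: data must have 2 or 3 axes", call. = FALSE)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("binary_mask: numeric data must contain only 0/1", call. = FALSE)
    data <- array(data != 0, dim(data))
  }
  if (!is.logical(data) || anyNA(data))
    stop("binary_mask: data must be logical with no NA", call. = FALSE)
  if (is.null(spacing)) spacing <- rep(1, nd)
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd || any(spacing <= 0))
    stop("binary_mask: spacing must be strictly positive per axis", call. = FALSE)
  structure(list(data = data, spacing = spacing,
                 origin = origin, direction = direction),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " | spacing (mm): ", paste(format(x$spacing), collapse = ", "),
      " | range: [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " | foreground voxels: ", sum(x$data), "\n", sep = "")
  invisible(x)
}

# internal: accept image_volume / binary_mask / bare array, return plain array
as_vol_array <- function(x) {
  if (inherits(x, "image_volume") || inherits(x, "binary_mask")) return(x$data)
  if (is.array(x) || is.matrix(x)) return(as.array(x))
  stop("expected an image_volume, binary_mask, or array", call. = FALSE)
}

check_congruent <- function(x, y, what = "masks") {
  if (!identical(dim(as_vol_array(x)), dim(as_vol_array(y))))
    stop("shape mismatch: ", what, " must have identical dimensions",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a grayscale volume from disk
#'
#' Supports NIfTI-1 (`.nii` / `.nii.gz`) via RNifti and single-channel
#' 8/16-bit grayscale PNG for 2D fixtures. PNG images get unit spacing;
#' NIfTI spacing, origin and orientation are preserved.
#'
#' @param path Path to an existing `.nii`, `.nii.gz`, or `.png` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] == 1L) {
        arr <- arr[, , 1L]
      } else {
        stop("read_volume: multi-channel PNG is unsupported: ", path,
             call. = FALSE)
      }
    }
    return(image_volume(arr, spacing = c(1, 1)))
  }
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("read_volume: unsupported format (need .nii, .nii.gz, or .png): ",
         path, call. = FALSE)
  nif <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: unreadable NIfTI '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  arr <- as.array(nif)
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) { arr <- arr[, , , 1L]; nd <- 3L }
  if (!nd %in% c(2L, 3L))
    stop("read_volume: expected a 2D/3D single-channel image, got ", nd,
         " axes", call. = FALSE)
  sp <- RNifti::pixdim(nif)[seq_len(nd)]
  hdr <- RNifti::niftiHeader(nif)
  image_volume(arr, spacing = sp,
               origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z),
               direction = RNifti::xform(nif))
}

#' Write an image or mask volume to disk
#'
#' Masks are written as unsigned 8-bit 0/1 NIfTI for interoperability;
#' images as 32-bit float. PNG output (2D only) rescales nothing: mask
#' values 0/1 map to black/white.
#'
#' @param x An [image_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii`, `.nii.gz`, or `.png`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- as_vol_array(x)
  is_mask <- inherits(x, "binary_mask") || is.logical(arr)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("write_volume: parent directory does not exist: ", dir, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (length(dim(arr)) != 2L)
      stop("write_volume: PNG output supports 2D only", call. = FALSE)
    out <- if (is_mask) array(as.numeric(arr), dim(arr)) else arr
    png::writePNG(out, path)
    return(invisible(path))
  }
  sp <- if (inherits(x, "image_volume") || inherits(x, "binary_mask"))
    x$spacing else rep(1, length(dim(arr)))
  storage.mode(arr) <- "double"
  nif <- RNifti::asNifti(arr)
  RNifti::pixdim(nif) <- sp
  ok <- tryCatch({
    RNifti::writeNifti(nif, path,
                       datatype = if (is_mask) "uint8" else "float")
    TRUE
  }, error = function(e) {
    stop("write_volume: failed writing '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' @rdname write_volume
#' @param mask A [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "binary_mask"))
    mask <- binary_mask(as_vol_array(mask))
  write_volume(mask, path)
}

#' Z-score intensity normalization
#'
#' Rescales intensities to zero mean and unit standard deviation, the
#' standard pre-processing step before marker generation and encoding. The
#' standard deviation uses the population (divide-by-N) convention.
#'
#' @param img An [image_volume()] (or bare array).
#' @return An [image_volume()] with the same shape and metadata.
#' @examples
#' img <- image_volume(matrix(c(0, 2, 0, 2), 2, 2))
#' zscore_normalize(img)$data
#' @export
zscore_normalize <- function(img) {
  arr <- as_vol_array(img)
  n <- length(arr)
  if (n < 2L)
    stop("zscore_normalize: need at least 2 voxels", call. = FALSE)
  m <- mean(arr)
  s <- sqrt(mean((arr - m)^2))
  if (s == 0)
    stop("zscore_normalize: zero intensity variance (degenerate input)",
         call. = FALSE)
  out <- (arr - m) / s
  if (inherits(img, "image_volume"))
    image_volume(out, spacing = img$spacing, origin = img$origin,
                 direction = img$direction)
  else image_volume(out)
}

# internal: min-max rescale to [0, 1]; constant arrays map to 0
minmax01 <- function(arr) {
  r <- range(arr)
  if (r[2] == r[1]) return(array(0, dim(arr)))
  (arr - r[1]) / (r[2] - r[1])
}
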