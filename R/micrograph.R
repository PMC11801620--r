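#' Calibrated grayscale micrograph
#'
#' A `micrograph` bundles a 2D grid of grayscale intensities with its
#' physical pixel calibration. Intensities are held on a continuous 0-255
#' working scale regardless of the bit depth of the file they came from;
#' pixels are indexed `[row, col]`, 1-based, origin at the top-left, matching
#' base R matrix conventions. All sizes downstream (areas in nm^2, diameters
#' in nm) derive from `pixel_size`, so it must be supplied explicitly --
#' there is no default.
#'
#' @param pixels numeric matrix of intensities on the 0-255 scale.
#' @param pixel_size physical edge length of one pixel in nm (> 0).
#' @param image_id identifier string; defaults to `"image"`.
#' @return An object of class `micrograph`: a list with elements `image_id`,
#'   `pixels`, `pixel_size`.
#' @examples
#' m <- micrograph(matrix(128, 8, 8), pixel_size = 2)
#' dim(m$pixels)
#' @export
micrograph <- function(pixels, pixel_size, image_id = "image") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  stopifnot(nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive finite number (nm per pixel)",
         call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255)) {
    stop("micrograph intensities must be finite and within [0, 255]",
         call. = FALSE)
  }
  structure(
    list(image_id = as.character(image_id), pixels = pixels,
         pixel_size = as.numeric(pixel_size)),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %s: %d x %d px, %.3g nm/px, intensity [%.1f, %.1f]\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary fibril/background mask
#'
#' A `binary_mask` labels each pixel of a paired micrograph as fibril
#' (`TRUE`) or background (`FALSE`) and records where the labels came from:
#' a human reviewer, the classifier, or a reviewer consensus.
#'
#' @param pixels logical matrix (or 0/1 coercible) with `TRUE` = fibril.
#' @param provenance one of `"reviewer:<id>"`, `"model"`, `"consensus"`, or
#'   any descriptive string; stored verbatim.
#' @param image_id identifier string.
#' @return An object of class `binary_mask`.
#' @examples
#' bm <- binary_mask(matrix(c(TRUE, FALSE), 4, 4), provenance = "model")
#' sum(bm$pixels)
#' @export
binary_mask <- function(pixels, provenance = "model", image_id = "image") {
  pixels <- as.matrix(pixels)
  if (is.numeric(pixels)) {
    vals <- unique(as.vector(pixels))
    if (!all(vals %in% c(0, 1, 255))) {
      stop("numeric mask input must contain only 0/1 or 0/255 values",
           call. = FALSE)
    }
    pixels <- pixels > 0
  }
  if (!is.logical(pixels)) stop("mask pixels must be logical or 0/1", call. = FALSE)
  if (anyNA(pixels)) stop("mask pixels must not contain NA", call. = FALSE)
  structure(
    list(image_id = as.character(image_id), pixels = pixels,
         provenance = as.character(provenance)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s [%s]: %d x %d px, %d fibril px (%.1f%%)\n",
              x$image_id, x$provenance, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

# Decode a PNG/TIFF path to a [0,1] numeric matrix; collapses trivially gray
# RGB, drops an all-opaque alpha channel, errors on real color content.
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)", call. = FALSE)
  )
  if (length(dim(raw)) == 3) {
    nc <- dim(raw)[3]
    if (nc %in% c(2, 4)) { # gray+alpha or RGBA
      alpha <- raw[, , nc]
      if (any(alpha < 1)) stop("images with transparency are not supported", call. = FALSE)
      raw <- raw[, , -nc, drop = FALSE]
      nc <- dim(raw)[3]
    }
    if (nc == 1) {
      raw <- raw[, , 1]
    } else {
      # only trivially-gray RGB (all channels equal) collapses
      if (max(abs(raw[, , 1] - raw[, , 2])) > 1e-9 ||
          max(abs(raw[, , 1] - raw[, , 3])) > 1e-9) {
        stop("image has non-grayscale color content", call. = FALSE)
      }
      raw <- raw[, , 1]
    }
  }
  raw
}

#' Read a calibrated micrograph from a TIFF or PNG file
#'
#' Decodes an 8- or 16-bit single-channel raster (RGB files whose channels
#' are identical are accepted and collapsed) and rescales intensities
#' linearly to the 0-255 working scale: an 8-bit value v maps to v, a 16-bit
#' value v to v * 255 / 65535. The nm-per-pixel calibration is mandatory;
#' for TIFF inputs carrying an x-resolution tag in pixels per cm/inch it can
#' be recovered from the file by passing `pixel_size = NULL`, but absent a
#' usable tag that is an error, never a silent default.
#'
#' @param path path to a grayscale TIFF or PNG file.
#' @param pixel_size nm per pixel, or `NULL` to attempt TIFF tag recovery.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [micrograph].
#' @export
read_micrograph <- function(path, pixel_size, image_id = NULL) {
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  if (missing(pixel_size)) {
    stop("`pixel_size` is required (pass NULL to attempt TIFF tag recovery)",
         call. = FALSE)
  }
  if (is.null(pixel_size)) {
    pixel_size <- pixel_size_from_tiff(path)
    if (is.null(pixel_size)) {
      stop("no usable resolution tag in ", path,
           "; pass `pixel_size` explicitly", call. = FALSE)
    }
  }
  raw <- read_raster(path)
  micrograph(raw * 255, pixel_size = pixel_size, image_id = image_id)
}

# nm/px from a TIFF x-resolution tag (pixels per unit), when present.
pixel_size_from_tiff <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff")) return(NULL)
  info <- attributes(tiff::readTIFF(path, info = TRUE))
  res <- info$x.resolution
  unit <- info$resolution.unit
  if (is.null(res) || !is.numeric(res) || res <= 0) return(NULL)
  per_nm <- switch(as.character(unit %||% "inch"),
    inch = res / 2.54e7,
    cm = res / 1e7,
    return(NULL)
  )
  1 / per_nm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a binary mask from a TIFF or PNG file
#'
#' Any pixel above half intensity is taken as fibril, so both 0/1 and 0/255
#' codings decode identically.
#'
#' @param path path to the mask raster.
#' @param provenance provenance string stored on the mask.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [binary_mask].
#' @export
read_mask <- function(path, provenance = "reviewer:unknown", image_id = NULL) {
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  raw <- read_raster(path)
  binary_mask(raw > 0.5, provenance = provenance, image_id = image_id)
}

#' Write a binary mask as an 8-bit raster
#'
#' Fibril pixels are written as 255 and background as 0, the coding ImageJ
#' expects of a binary image, whatever the in-memory representation.
#'
#' @param mask a [binary_mask].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- matrix(as.numeric(mask$pixels), nrow(mask$pixels), ncol(mask$pixels))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    tif = ,
    tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Write a micrograph as an 8-bit raster
#'
#' Intensities on the 0-255 working scale are written as 8-bit gray values
#' (rounded). The nm/px calibration is not embedded; keep it in the run
#' configuration.
#'
#' @param m a [micrograph].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  img <- round(m$pixels) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    tif = ,
    tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# shared shape check
check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(what, " have mismatched dimensions: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"),
         call. = FALSE)
  }
  invisible(TRUE)
}
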