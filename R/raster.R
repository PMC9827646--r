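#' Raster image container
#'
#' A thin container for a 2D grayscale micrograph: a numeric matrix of
#' intensities (row 1 is the top row of the image), a bit depth, and an
#' optional spatial calibration in micrometers per pixel. Intensities are
#' stored on the native integer scale of the bit depth, i.e. `[0, 255]` for
#' 8-bit and `[0, 65535]` for 16-bit data.
#'
#' @param pixels numeric matrix of intensities, row-major with row 1 at the
#'   top.
#' @param bit_depth integer, 8 or 16.
#' @param scale micrometers per pixel (> 0), or `NULL` if uncalibrated.
#'   A calibration is only required once geometry is converted to physical
#'   units for the finite element stage.
#' @return an object of class `raster_image`.
#' @examples
#' img <- raster_image(matrix(0:255, 16, 16), bit_depth = 8)
#' dim(img$pixels)
#' @export
raster_image <- function(pixels, bit_depth = 8L, scale = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("image must be at least 1x1")
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxv))
    stop("intensities outside [0, ", maxv, "]")
  if (!is.null(scale)) {
    scale <- as.numeric(scale)
    if (!is.finite(scale) || scale <= 0) stop("scale must be > 0 um/px")
  }
  structure(list(pixels = pixels, bit_depth = bit_depth, scale = scale),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d, %d-bit, scale = %s um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (is.null(x$scale)) "NA" else format(x$scale)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Read a micrograph from a PNG or TIFF file
#'
#' RGB or RGBA images are reduced to grayscale by the unweighted mean of the
#' color channels; an alpha channel is dropped. Sample values are rescaled
#' from the file's `[0, 1]` convention to the integer range of `bit_depth`.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param scale optional micrometers per pixel to attach to the image.
#' @param bit_depth target bit depth of the returned image (default 8).
#' @return a [raster_image()].
#' @export
read_raster <- function(path, scale = NULL, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    else arr <- arr[, , 1]
  }
  maxv <- 2^as.integer(bit_depth) - 1
  raster_image(round(arr * maxv), bit_depth = bit_depth, scale = scale)
}

#' Write a grayscale or RGB raster to a PNG file
#'
#' @param img a [raster_image()], a numeric matrix on `[0, 255]`, or an
#'   `H x W x 3` RGB array on `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  if (inherits(img, "raster_image")) {
    maxv <- 2^img$bit_depth - 1
    png::writePNG(img$pixels / maxv, path)
  } else {
    png::writePNG(img / 255, path)
  }
  invisible(path)
}

# internal: coerce raster_image or bare matrix to an intensity matrix
px <- function(img) {
  if (inherits(img, "raster_image")) img$pixels else as.matrix(img)
}
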