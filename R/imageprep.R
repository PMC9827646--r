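#' Convert an image to 8-bit
#'
#' Linearly maps the observed intensity range `[min, max]` onto `[0, 255]`
#' with rounding, the usual first step before segmenting a 16-bit
#' micrograph. Images that are already 8-bit are returned unchanged, and a
#' constant image maps to 0.
#'
#' @param img a [raster_image()].
#' @return an 8-bit [raster_image()] with the same dimensions and scale.
#' @examples
#' img <- raster_image(matrix(c(100, 200, 300, 300), 2, 2), bit_depth = 16)
#' to_8bit(img)$pixels
#' @export
to_8bit <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$bit_depth == 8L) return(img)
  p <- img$pixels
  lo <- min(p); hi <- max(p)
  out <- if (hi > lo) round(255 * (p - lo) / (hi - lo)) else p * 0
  raster_image(out, bit_depth = 8L, scale = img$scale)
}

#' Sharpen an 8-bit image
#'
#' 3x3 sharpening convolution with center weight 12, neighbor weights -1 and
#' divisor 4, the kernel used by common microscopy image editors. Borders
#' are handled by edge replication and the result is clipped to `[0, 255]`.
#'
#' @param img an 8-bit [raster_image()].
#' @return sharpened [raster_image()].
#' @export
sharpen <- function(img) {
  stopifnot(inherits(img, "raster_image"), img$bit_depth == 8L)
  k <- matrix(-1, 3, 3); k[2, 2] <- 12
  out <- cpp_conv3(img$pixels, k / 4)
  raster_image(pmin(pmax(round(out), 0), 255), 8L, img$scale)
}

#' Window brightness and contrast
#'
#' Maps the display window `[display_min, display_max]` linearly onto
#' `[0, 255]`, clipping outside the window: intensities at or below the
#' minimum become 0 and intensities at or above the maximum become 255.
#' A window such as (-10, 127) boosts the contrast between dark cell walls
#' and bright cell interiors ahead of segmentation; the lower bound may be
#' negative.
#'
#' @param img an 8-bit [raster_image()].
#' @param display_min,display_max window endpoints; `display_min <
#'   display_max`.
#' @return contrast-stretched [raster_image()].
#' @examples
#' img <- raster_image(matrix(c(0, 58.5, 127, 200), 2, 2))
#' rescale_contrast(img, -10, 127)$pixels
#' @export
rescale_contrast <- function(img, display_min = -10, display_max = 127) {
  stopifnot(inherits(img, "raster_image"))
  if (display_min >= display_max)
    stop("invalid window: display_min must be < display_max")
  out <- round(255 * (img$pixels - display_min) / (display_max - display_min))
  raster_image(pmin(pmax(out, 0), 255), 8L, img$scale)
}

#' Despeckle (repeated 3x3 median filter)
#'
#' Removes salt-and-pepper noise left by sectioning debris. Each pass
#' replaces every pixel by the median of its 3x3 neighborhood, with edge
#' replication at the borders; micrograph cleanup conventionally uses three
#' passes.
#'
#' @param img a [raster_image()].
#' @param repeats number of filter passes (>= 0).
#' @return filtered [raster_image()].
#' @export
despeckle <- function(img, repeats = 3L) {
  stopifnot(inherits(img, "raster_image"))
  repeats <- as.integer(repeats)
  if (repeats < 0) stop("repeats must be >= 0")
  if (repeats == 0) return(img)
  raster_image(cpp_median3(img$pixels, repeats), img$bit_depth, img$scale)
}

#' Standard preprocessing chain
#'
#' Convenience wrapper running 8-bit conversion, optional sharpening,
#' contrast windowing and repeated despeckling in the conventional order.
#'
#' @param img a [raster_image()].
#' @param display_min,display_max contrast window (defaults -10 and 127);
#'   micrographs differ, so per-image adjustment is expected.
#' @param despeckle_repeats median filter passes (default 3).
#' @param sharpen apply the sharpening convolution (default `TRUE`).
#' @return preprocessed 8-bit [raster_image()].
#' @export
preprocess <- function(img, display_min = -10, display_max = 127,
                       despeckle_repeats = 3L, sharpen = TRUE) {
  out <- to_8bit(img)
  if (isTRUE(sharpen)) out <- sharpen(out)
  out <- rescale_contrast(out, display_min, display_max)
  despeckle(out, despeckle_repeats)
}
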