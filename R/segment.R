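#' Band threshold an 8-bit image into a wall mask
#'
#' A pixel is classed as cell wall iff `lo <= intensity <= hi` (both bounds
#' inclusive). Stained walls are dark and interiors bright, so the first
#' segmentation pass conventionally uses a wide band such as `[0, 175]`.
#'
#' @param img an 8-bit [raster_image()].
#' @param lo,hi inclusive intensity band; `lo <= hi`.
#' @return logical matrix, `TRUE` on wall pixels.
#' @export
band_threshold <- function(img, lo = 0, hi = 175) {
  stopifnot(inherits(img, "raster_image"), img$bit_depth == 8L)
  if (lo > hi) stop("invalid band: lo must be <= hi")
  img$pixels >= lo & img$pixels <= hi
}

#' Clean a binary wall mask
#'
#' Automated replacement for manual freehand/invert noise removal: deletes
#' small isolated wall components (8-connected specks with area below
#' `min_speck_area`) and fills small fully enclosed background holes
#' (4-connected, area below `max_hole_area`). Background regions touching
#' the image border are never treated as holes.
#'
#' @param mask logical wall mask.
#' @param min_speck_area wall components strictly smaller than this (in
#'   pixels) are removed.
#' @param max_hole_area enclosed background holes strictly smaller than this
#'   are filled.
#' @return cleaned logical mask.
#' @export
clean_mask <- function(mask, min_speck_area = 25, max_hole_area = 25) {
  mask <- as_mask(mask)
  if (min_speck_area > 0 && any(mask)) {
    lab <- cpp_label_components(mask, 8L)
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < min_speck_area)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  if (max_hole_area > 0 && any(!mask)) {
    lab <- cpp_label_components(!mask, 4L)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    areas <- tabulate(lab[lab > 0])
    fill <- setdiff(which(areas < max_hole_area), border)
    if (length(fill)) mask[lab %in% fill] <- TRUE
  }
  mask
}

#' Euclidean distance map of a wall mask
#'
#' Assigns every wall (foreground) pixel its exact Euclidean distance, in
#' pixel units, to the center of the nearest background pixel; background
#' pixels are 0. The image border does not count as background, so walls
#' running into the crop edge are not artificially thinned.
#'
#' @param mask logical wall mask with at least one background pixel.
#' @return numeric matrix of distances (pixel units).
#' @export
edm <- function(mask) {
  mask <- as_mask(mask)
  if (!any(!mask)) stop("distance map undefined: mask has no background pixel")
  sqrt(cpp_edt_sq(mask))
}

#' Thin walls by distance-map thresholding
#'
#' Second-pass binarization of the distance map: keeps only wall pixels at
#' distance `thin_keep_min` or more from the background, reducing wall
#' ribbons to thin center bands while keeping neighboring cells from merging
#' into each other. With `thin_keep_min = 0` the mask is unchanged.
#'
#' @param mask logical wall mask.
#' @param d distance map computed from `mask` by [edm()] (computed if
#'   missing).
#' @param thin_keep_min minimum distance (px) a wall pixel must have to
#'   survive.
#' @return logical mask, a subset of `mask`.
#' @export
thin_walls <- function(mask, d = NULL, thin_keep_min = 2) {
  mask <- as_mask(mask)
  if (thin_keep_min < 0) stop("thin_keep_min must be >= 0")
  if (is.null(d)) d <- edm(mask)
  mask & (d >= thin_keep_min)
}

#' Train a two-class pixel classifier from scribbles
#'
#' Stand-in for interactive machine-learning segmentation: the user paints a
#' few wall and interior pixels, a random forest is trained on per-pixel
#' features, and the whole image is then classified by [classify()].
#' Features are the raw intensity plus, at each smoothing scale, the
#' Gaussian-smoothed intensity and its gradient magnitude.
#'
#' @param img an 8-bit [raster_image()].
#' @param scribbles integer matrix the size of the image: 0 = unlabeled,
#'   1 = wall, 2 = interior.
#' @param scales Gaussian smoothing sigmas for the feature bank (px).
#' @param ntree random forest size.
#' @param seed integer seed making training deterministic; recorded in the
#'   classifier.
#' @return an object of class `pixel_classifier`.
#' @export
train_classifier <- function(img, scribbles, scales = c(1, 2, 4),
                             ntree = 100L, seed = 1L) {
  stopifnot(inherits(img, "raster_image"), img$bit_depth == 8L)
  scribbles <- as.matrix(scribbles)
  if (!all(dim(scribbles) == dim(img$pixels)))
    stop("scribbles must match image dimensions")
  n_wall <- sum(scribbles == 1)
  n_int <- sum(scribbles == 2)
  if (n_wall < 1 || n_int < 1)
    stop("insufficient training data: need >= 1 labeled pixel per class")
  feats <- pixel_features(img$pixels, scales)
  idx <- which(scribbles == 1 | scribbles == 2)
  x <- feats[idx, , drop = FALSE]
  y <- factor(ifelse(scribbles[idx] == 1, "wall", "interior"),
              levels = c("wall", "interior"))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  acc <- mean(stats::predict(fit, x) == y)
  structure(list(model = fit, scales = scales, seed = seed,
                 n_train = length(idx), train_accuracy = acc),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> random forest, %d training px, scales {%s}, seed %d\n",
    x$n_train, paste(x$scales, collapse = ", "), x$seed))
  cat(sprintf("  training accuracy %.3f\n", x$train_accuracy))
  invisible(x)
}

#' Classify every pixel of an image
#'
#' Applies a trained [train_classifier()] model to the whole image.
#' Prediction is deterministic: class votes are converted to wall
#' probability and ties are broken toward the wall class.
#'
#' @param img an 8-bit [raster_image()].
#' @param clf a `pixel_classifier`.
#' @return logical wall mask.
#' @export
classify <- function(img, clf) {
  stopifnot(inherits(img, "raster_image"), inherits(clf, "pixel_classifier"))
  feats <- pixel_features(img$pixels, clf$scales)
  p <- stats::predict(clf$model, feats, type = "prob")[, "wall"]
  matrix(p >= 0.5, nrow(img$pixels), ncol(img$pixels))
}

# per-pixel feature bank: raw intensity, smoothed intensity and gradient
# magnitude at each scale; rows in column-major pixel order
pixel_features <- function(p, scales) {
  cols <- list(intensity = as.vector(p))
  for (s in scales) {
    sm <- gaussian_smooth(p, s)
    cols[[paste0("gauss_", s)]] <- as.vector(sm)
    gr <- row_gradient(sm)
    gc <- t(row_gradient(t(sm)))
    cols[[paste0("gradmag_", s)]] <- as.vector(sqrt(gr^2 + gc^2))
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

# separable Gaussian smoothing with edge replication
gaussian_smooth <- function(p, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_rows <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (t in -r:r) {
      rows <- pmin(pmax(seq_len(nr) + t, 1L), nr)
      out <- out + k[t + r + 1] * m[rows, , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(p))))
}

# central-difference gradient along rows, replicated edges
row_gradient <- function(m) {
  nr <- nrow(m)
  up <- m[pmin(pmax(seq_len(nr) - 1, 1L), nr), , drop = FALSE]
  dn <- m[pmin(pmax(seq_len(nr) + 1, 1L), nr), , drop = FALSE]
  (dn - up) / 2
}

# internal: validate/coerce a logical mask
as_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  mask
}
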