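#' Count cells in a partition
#'
#' @param partition a `label_map`.
#' @return number of distinct nonzero labels.
#' @export
count_cells <- function(partition) {
  lab <- unclass_label(partition)
  length(unique(lab[lab > 0]))
}

#' Per-cell area records
#'
#' One record per cell: pixel area, physical area (`area_um2 = area_px *
#' scale^2`), centroid (in x = column, y = row-from-top coordinates) and a
#' border-touching flag. Border cells are included but flagged, as cells cut
#' by the image edge are only partially measured.
#'
#' @param partition a `label_map`.
#' @param scale um per pixel (> 0).
#' @return data frame with columns `label`, `area_px`, `area_um2`,
#'   `centroid_x`, `centroid_y`, `border_touching`.
#' @export
cell_areas <- function(partition, scale = 1) {
  if (!is.numeric(scale) || scale <= 0)
    stop("invalid calibration: scale must be > 0 um/px")
  lab <- unclass_label(partition)
  labels <- sort(unique(lab[lab > 0]))
  border <- attr(partition, "border_touching")
  if (is.null(border))
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  recs <- lapply(labels, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    data.frame(label = k, area_px = nrow(w),
               area_um2 = nrow(w) * scale^2,
               centroid_x = mean(w[, 2]), centroid_y = mean(w[, 1]),
               border_touching = k %in% border)
  })
  do.call(rbind, recs)
}

#' Normalized cell-size histogram
#'
#' Equal-width bins spanning the observed area range, with frequencies
#' normalized to the total number of cells (so they sum to 1). The
#' right-most bin is closed.
#'
#' @param records data frame from [cell_areas()].
#' @param n_bins number of bins (default 10).
#' @param unit `"um2"` or `"px2"`: which area column to bin.
#' @return list with `bin_edges` (length `n_bins + 1`) and `frequencies`
#'   (length `n_bins`).
#' @export
size_histogram <- function(records, n_bins = 10L, unit = c("um2", "px2")) {
  unit <- match.arg(unit)
  if (is.null(records) || nrow(records) < 1)
    stop("nothing to histogram: no cell records")
  if (n_bins < 1) stop("n_bins must be >= 1")
  a <- if (unit == "um2") records$area_um2 else records$area_px
  lo <- min(a); hi <- max(a)
  if (hi == lo) hi <- lo + 1  # degenerate range: one bin catches everything
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(findInterval(a, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  list(bin_edges = edges, frequencies = counts / length(a))
}

#' Color cells by size rank
#'
#' Renders the partition with each cell filled by a color from a blue
#' (smallest) to red (largest) map indexed by area rank; tied areas share a
#' rank and hence a color. Wall (zero-label) pixels are black.
#'
#' @param partition a `label_map`.
#' @param records data frame from [cell_areas()] covering all labels.
#' @return `H x W x 3` numeric array on `[0, 255]`.
#' @export
color_by_size <- function(partition, records = cell_areas(partition)) {
  lab <- unclass_label(partition)
  labels <- sort(unique(lab[lab > 0]))
  if (!all(labels %in% records$label))
    stop("records must cover all labels in the partition")
  records <- records[match(labels, records$label), ]
  rk <- match(records$area_px, sort(unique(records$area_px)))  # dense rank
  f <- if (max(rk) > 1) (rk - 1) / (max(rk) - 1) else rep(0, length(rk))
  ramp <- grDevices::colorRamp(c("blue", "red"))(f)  # rows: labels
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  lut <- matrix(0, max(labels), 3)
  lut[labels, ] <- ramp
  nz <- lab > 0
  for (ch in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    plane[nz] <- lut[lab[nz], ch]
    out[, , ch] <- plane
  }
  out
}

#' Write morphometric outputs to a directory
#'
#' Writes `cells.csv`, `histogram.csv` and `cells_by_size.png`.
#'
#' @param partition a `label_map`.
#' @param scale um per pixel.
#' @param n_bins histogram bins.
#' @param out_dir output directory (created if missing).
#' @return the cell records, invisibly.
#' @export
write_morphometrics <- function(partition, scale = 1, n_bins = 10L,
                                out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- cell_areas(partition, scale)
  utils::write.csv(recs, file.path(out_dir, "cells.csv"), row.names = FALSE)
  h <- size_histogram(recs, n_bins)
  utils::write.csv(
    data.frame(bin_lo = h$bin_edges[-length(h$bin_edges)],
               bin_hi = h$bin_edges[-1],
               frequency = h$frequencies),
    file.path(out_dir, "histogram.csv"), row.names = FALSE)
  write_raster(color_by_size(partition, recs),
               file.path(out_dir, "cells_by_size.png"))
  invisible(recs)
}
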