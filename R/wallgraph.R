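#' Wall graph container
#'
#' The digitized cell-wall geometry: junction vertices joined by polyline
#' walls, each wall optionally carrying its own thickness. Coordinates are
#' in pixels or micrometers according to `unit`; `scale` records the
#' calibration (um per px) used or needed for conversion.
#'
#' @param vertices data frame with columns `x`, `y`; the row number is the
#'   vertex id.
#' @param walls list; each wall is a list with `v` (length-2 vertex ids),
#'   `points` (n x 2 matrix of polyline coordinates, n >= 2) and
#'   `thickness` (um, or `NA`).
#' @param unit `"px"` or `"um"`.
#' @param scale micrometers per pixel, or `NULL` when unknown.
#' @return an object of class `wall_graph`.
#' @export
new_wall_graph <- function(vertices, walls, unit = c("um", "px"),
                           scale = NULL) {
  unit <- match.arg(unit)
  vertices <- as.data.frame(vertices)
  stopifnot(all(c("x", "y") %in% names(vertices)))
  for (w in walls) {
    if (length(w$v) != 2 || any(w$v < 1) || any(w$v > nrow(vertices)))
      stop("wall endpoints must be valid vertex ids")
    if (!is.matrix(w$points) || nrow(w$points) < 2)
      stop("wall polylines need at least 2 points")
    if (polyline_length(w$points) <= 0) stop("zero-length wall")
  }
  structure(list(vertices = vertices, walls = walls, unit = unit,
                 scale = scale),
            class = "wall_graph")
}

#' @export
print.wall_graph <- function(x, ...) {
  cat(sprintf("<wall_graph> %d vertices, %d walls [%s]\n",
              nrow(x$vertices), length(x$walls), x$unit))
  th <- wall_thicknesses(x)
  if (any(!is.na(th)))
    cat(sprintf("  thickness: %s um\n",
                paste(format(unique(round(th[!is.na(th)], 3))), collapse = ", ")))
  invisible(x)
}

#' Wall lengths of a graph
#' @param g a `wall_graph`.
#' @return numeric vector, one length per wall (graph units).
#' @export
wall_lengths <- function(g) {
  vapply(g$walls, function(w) polyline_length(w$points), numeric(1))
}

#' Wall thicknesses of a graph
#' @param g a `wall_graph`.
#' @return numeric vector (um), `NA` where unset.
#' @export
wall_thicknesses <- function(g) {
  vapply(g$walls, function(w) {
    if (is.null(w$thickness)) NA_real_ else as.numeric(w$thickness)
  }, numeric(1))
}

#' Set a uniform wall thickness
#' @param g a `wall_graph`.
#' @param thickness wall thickness in um, recycled across walls.
#' @return the modified graph.
#' @export
set_wall_thickness <- function(g, thickness) {
  thickness <- rep_len(thickness, length(g$walls))
  for (i in seq_along(g$walls)) g$walls[[i]]$thickness <- thickness[i]
  g
}

#' Convert wall-graph coordinates from pixels to micrometers
#' @param g a `wall_graph` in pixel units with a known `scale`.
#' @param scale um per px; defaults to the scale stored in the graph.
#' @return the graph in um units.
#' @export
graph_to_um <- function(g, scale = g$scale) {
  if (g$unit == "um") return(g)
  if (is.null(scale)) stop("uncalibrated geometry: no um-per-pixel scale")
  g$vertices$x <- g$vertices$x * scale
  g$vertices$y <- g$vertices$y * scale
  g$walls <- lapply(g$walls, function(w) {
    w$points <- w$points * scale
    w
  })
  g$unit <- "um"
  g$scale <- scale
  g
}

#' Serialize a wall graph to JSON
#' @param g a `wall_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wall_graph <- function(g, path) {
  obj <- list(
    unit = g$unit,
    scale = g$scale,
    vertices = g$vertices[, c("x", "y")],
    walls = lapply(g$walls, function(w) list(
      v = as.integer(w$v),
      thickness = if (is.null(w$thickness)) NA else w$thickness,
      points = unname(as.matrix(w$points)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a wall graph from JSON
#' @param path file written by [write_wall_graph()].
#' @return a `wall_graph`.
#' @export
read_wall_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  walls <- lapply(seq_len(if (is.data.frame(obj$walls)) nrow(obj$walls)
                          else length(obj$walls)), function(i) {
    w <- if (is.data.frame(obj$walls)) {
      list(v = obj$walls$v[[i]], thickness = obj$walls$thickness[[i]],
           points = obj$walls$points[[i]])
    } else obj$walls[[i]]
    list(v = as.integer(w$v),
         thickness = if (is.null(w$thickness) || all(is.na(w$thickness)))
           NA_real_ else as.numeric(w$thickness),
         points = matrix(as.numeric(w$points), ncol = 2))
  })
  new_wall_graph(as.data.frame(obj$vertices), walls, unit = obj$unit,
                 scale = if (is.null(obj$scale)) NULL else obj$scale)
}

#' Write the walls of a graph as a CSV edge list
#' @param g a `wall_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wall_csv <- function(g, path) {
  df <- data.frame(
    wall = seq_along(g$walls),
    v1 = vapply(g$walls, function(w) w$v[1], numeric(1)),
    v2 = vapply(g$walls, function(w) w$v[2], numeric(1)),
    length = wall_lengths(g),
    thickness = wall_thicknesses(g))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# internal: arc length of an n x 2 polyline
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# internal: Douglas-Peucker polyline simplification at tolerance `tol`
simplify_polyline <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    idx <- (i + 1):(j - 1)
    dv <- pts[idx, , drop = FALSE]
    if (len2 == 0) {
      d <- sqrt((dv[, 1] - a[1])^2 + (dv[, 2] - a[2])^2)
    } else {
      # perpendicular distance to the segment's infinite line
      d <- abs(ab[1] * (a[2] - dv[, 2]) - (a[1] - dv[, 1]) * ab[2]) / sqrt(len2)
    }
    kmax <- which.max(d)
    if (d[kmax] > tol) {
      m <- idx[kmax]
      keep[m] <- TRUE
      stack <- c(stack, list(c(i, m)), list(c(m, j)))
    }
  }
  pts[keep, , drop = FALSE]
}
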