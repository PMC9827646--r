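#' Label cell interiors
#'
#' 4-connected components of the non-wall pixels of a thinned mask, labeled
#' `1..N` in raster-scan order (row-major from the top row) of each
#' component's first pixel. Labels touching the image edge are flagged,
#' since partially imaged border cells are less reliably modeled.
#'
#' @param thin_mask logical wall mask after thinning.
#' @return integer `label_map` matrix (0 = wall) with attribute
#'   `border_touching`, an integer vector of flagged labels.
#' @export
interior_labels <- function(thin_mask) {
  thin_mask <- as_mask(thin_mask)
  lab <- cpp_label_components(!thin_mask, 4L)
  if (max(lab) == 0) stop("empty segmentation: no interior regions")
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  structure(lab, border_touching = sort(border[border > 0]),
            class = c("label_map", "matrix"))
}

#' Ultimate eroded points of each cell
#'
#' For every labeled cell, computes the Euclidean distance of its pixels to
#' the nearest non-cell pixel and returns the regional maxima: the last
#' points to survive uniform erosion, used as cell-center seeds. A connected
#' plateau of equal maxima yields a single point at its centroid, rounded to
#' the nearest pixel of the plateau.
#'
#' @param interiors a `label_map` from [interior_labels()].
#' @return data frame with columns `label`, `row`, `col`, `dist` (one or
#'   more rows per cell; multi-lobed cells yield several points).
#' @export
ueps <- function(interiors) {
  lab <- unclass_label(interiors)
  nlab <- max(lab)
  if (nlab < 1) stop("no labeled cells")
  out <- vector("list", nlab)
  nr <- nrow(lab); nc <- ncol(lab)
  for (k in seq_len(nlab)) {
    w <- which(lab == k, arr.ind = TRUE)
    if (nrow(w) == 0) next
    r0 <- max(1L, min(w[, 1]) - 1L); r1 <- min(nr, max(w[, 1]) + 1L)
    c0 <- max(1L, min(w[, 2]) - 1L); c1 <- min(nc, max(w[, 2]) + 1L)
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == k
    # pad so that pixels outside the window count as non-cell
    padded <- matrix(FALSE, nrow(sub) + 2, ncol(sub) + 2)
    padded[2:(nrow(sub) + 1), 2:(ncol(sub) + 1)] <- sub
    d <- cpp_edt_sq(padded)
    cand <- regional_maxima(d, padded)
    for (pl in cand) {
      cen <- colMeans(pl)
      pick <- pl[which.min((pl[, 1] - round(cen[1]))^2 +
                             (pl[, 2] - round(cen[2]))^2), ]
      rr <- round(cen[1]); cc <- round(cen[2])
      if (!any(pl[, 1] == rr & pl[, 2] == cc)) { rr <- pick[1]; cc <- pick[2] }
      out[[k]] <- rbind(out[[k]],
                        data.frame(label = k,
                                   row = r0 + rr - 2L, col = c0 + cc - 2L,
                                   dist = sqrt(d[pl[1, 1], pl[1, 2]])))
    }
  }
  do.call(rbind, out)
}

# connected plateaus of regional maxima of d restricted to fg pixels: the
# 8-connected components of equal value none of whose neighbors is higher.
# A plateau adjacent to an equal-valued pixel belongs to the same iso-level
# component, so a ridge leading upward disqualifies the whole component.
# Returns a list of m x 2 (row, col) matrices.
regional_maxima <- function(d, fg) {
  nr <- nrow(d); nc <- ncol(d)
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  center <- d[inner_r, inner_c]
  has_higher <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    has_higher[inner_r, inner_c] <- has_higher[inner_r, inner_c] |
      (d[inner_r + di, inner_c + dj] > center)
  }
  # iso-level components: label fg, then split components mixing values by
  # flooding equal-valued neighbors only
  out <- list()
  seen <- matrix(FALSE, nr, nc)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  cand <- which(fg & !has_higher & !seen, arr.ind = TRUE)
  for (s in seq_len(nrow(cand))) {
    i0 <- cand[s, 1]; j0 <- cand[s, 2]
    if (seen[i0, j0]) next
    v <- d[i0, j0]
    queue <- matrix(c(i0, j0), 1, 2)
    seen[i0, j0] <- TRUE
    plateau <- queue
    is_max <- !has_higher[i0, j0]
    while (nrow(queue)) {
      nxt <- NULL
      for (q in seq_len(nrow(queue))) {
        ii <- queue[q, 1] + offs$di; jj <- queue[q, 2] + offs$dj
        ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
        for (t in which(ok)) {
          if (fg[ii[t], jj[t]] && !seen[ii[t], jj[t]] &&
                d[ii[t], jj[t]] == v) {
            seen[ii[t], jj[t]] <- TRUE
            if (has_higher[ii[t], jj[t]]) is_max <- FALSE
            nxt <- rbind(nxt, c(ii[t], jj[t]))
          }
        }
      }
      if (is.null(nxt)) break
      plateau <- rbind(plateau, nxt)
      queue <- nxt
    }
    if (is_max) out[[length(out) + 1]] <- plateau
  }
  out
}

#' Voronoi partition by nearest particle
#'
#' Assigns every pixel of the image to the labeled particle whose nearest
#' pixel (center-to-center Euclidean distance) is closest, the digital
#' analogue of growing each cell until it collides with its neighbors.
#' Ties are broken toward the smaller label. The output contains no zero
#' labels.
#'
#' @param interiors a `label_map` of particles (cell interiors).
#' @return full-coverage `label_map` of the same shape.
#' @export
voronoi_partition <- function(interiors) {
  lab <- unclass_label(interiors)
  if (max(lab) < 1) stop("no labeled particles")
  res <- cpp_nearest_label(lab)
  out <- res$labels
  border <- unique(c(out[1, ], out[nrow(out), ], out[, 1], out[, ncol(out)]))
  structure(out, border_touching = sort(border[border > 0]),
            class = c("label_map", "matrix"))
}

#' Boundary skeleton of a partition
#'
#' Extracts the inter-region boundaries of a full Voronoi partition as a
#' one-pixel-wide curve network: a pixel is a boundary candidate iff its
#' 8-neighborhood contains a larger label (so each wall lies on the
#' smaller-label side), and the candidate set is then morphologically
#' thinned to guarantee unit width.
#'
#' @param partition full-coverage `label_map` from [voronoi_partition()].
#' @return logical mask of skeleton (wall) pixels.
#' @export
boundary_skeleton <- function(partition) {
  lab <- unclass_label(partition)
  nr <- nrow(lab); nc <- ncol(lab)
  cand <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    cand <- cand | (lab[ri, cj, drop = FALSE] > lab)
  }
  # protect frame pixels: thinning must not retract a wall end off the
  # image border, which would open a passage between two border cells
  protect <- matrix(FALSE, nr, nc)
  protect[c(1, nr), ] <- TRUE
  protect[, c(1, nc)] <- TRUE
  cpp_thin(cand, protect)
}

#' Extract the wall graph from a skeleton
#'
#' Separates the thinned boundary network into individual cell walls at
#' their junctions. Skeleton pixels with three or more skeleton neighbors
#' (8-connected) are junction pixels; each 8-connected cluster of junction
#' pixels is merged into a single vertex at its centroid, path endpoints
#' become vertices, and every maximal skeleton path between vertices becomes
#' a wall. Polylines are simplified by Douglas-Peucker; closed loops without
#' junctions become a single wall with coincident end vertices.
#'
#' Pixel `(row i, col j)` maps to coordinates `x = j`, `y = nrow - i + 1`
#' (y increases upward).
#'
#' @param skeleton logical unit-width skeleton mask.
#' @param scale um per pixel; when given, the graph is returned in um.
#' @param simplify_tol Douglas-Peucker tolerance in pixels (default 0.75).
#' @return a [new_wall_graph()] object.
#' @export
wall_graph <- function(skeleton, scale = NULL, simplify_tol = 0.75) {
  sk <- as_mask(skeleton)
  nr <- nrow(sk); nc <- ncol(sk)
  if (nr >= 2 && nc >= 2) {
    blk <- sk[-nr, -nc] & sk[-1, -nc] & sk[-nr, -1] & sk[-1, -1]
    if (any(blk)) stop("non-unit-width skeleton: thinning failure (2x2 block)")
  }
  pix <- which(sk, arr.ind = TRUE)
  if (nrow(pix) == 0)
    return(new_wall_graph(data.frame(x = numeric(), y = numeric()),
                          list(), unit = if (is.null(scale)) "px" else "um",
                          scale = scale))
  idx <- matrix(0L, nr, nc)
  idx[sk] <- seq_len(nrow(pix))
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  at <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out <- integer(length(i))
    out[ok] <- idx[cbind(i[ok], j[ok])]
    out
  }
  # reduced skeleton adjacency: a diagonal link is redundant (a stair-step
  # shortcut, not a true branch) when the two pixels already share an
  # orthogonal skeleton neighbor
  nbrs <- function(i, j) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ids <- at(ii, jj)
    diag_red <- offs[, 1] != 0 & offs[, 2] != 0 &
      (at(rep(i, 8), jj) > 0 | at(ii, rep(j, 8)) > 0)
    ids[ids > 0 & !diag_red]
  }
  adj <- lapply(seq_len(nrow(pix)), function(p) nbrs(pix[p, 1], pix[p, 2]))
  deg <- lengths(adj)

  # vertices: junction clusters (centroids), then endpoints
  jn <- deg >= 3
  jmask <- matrix(FALSE, nr, nc)
  jmask[pix[jn, , drop = FALSE]] <- TRUE
  jlab <- cpp_label_components(jmask, 8L)
  vx <- list(); vy <- list()
  vertex_of <- integer(nrow(pix))  # 0 = regular path pixel
  nclust <- max(jlab)
  for (k in seq_len(nclust)) {
    w <- which(jlab == k, arr.ind = TRUE)
    vx[[k]] <- mean(w[, 2]); vy[[k]] <- mean(nr - w[, 1] + 1)
    vertex_of[idx[w]] <- k
  }
  nv <- nclust
  for (p in which(deg <= 1)) {
    nv <- nv + 1L
    vx[[nv]] <- pix[p, 2]; vy[[nv]] <- nr - pix[p, 1] + 1
    vertex_of[p] <- nv
  }

  coord <- cbind(x = pix[, 2], y = nr - pix[, 1] + 1)
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  walls <- list()
  add_wall <- function(v1, v2, pts) {
    pts <- simplify_polyline(pts, simplify_tol)
    if (polyline_length(pts) <= 0) return(invisible())
    walls[[length(walls) + 1L]] <<- list(v = c(v1, v2), points = pts,
                                         thickness = NA_real_)
  }
  trace_from <- function(p, q) {
    # walk from vertex pixel p through q until the next vertex pixel
    path <- c(p, q)
    assign(ekey(p, q), TRUE, envir = used)
    prev <- p
    while (vertex_of[q] == 0L) {
      nq <- adj[[q]]
      nxt <- nq[nq != prev]
      if (length(nxt) == 0) break               # dead end (shouldn't happen)
      if (length(nxt) > 1) {
        # prefer an unused edge; ties toward vertex pixels
        unused <- nxt[!vapply(nxt, function(r)
          exists(ekey(q, r), envir = used), logical(1))]
        if (length(unused)) nxt <- unused
        vfirst <- nxt[vertex_of[nxt] != 0L]
        nxt <- if (length(vfirst)) vfirst[1] else nxt[1]
      }
      assign(ekey(q, nxt), TRUE, envir = used)
      path <- c(path, nxt)
      prev <- q
      q <- nxt
    }
    path
  }
  for (p in order(vertex_of == 0L)) {         # vertex pixels first
    if (vertex_of[p] == 0L) next
    for (q in adj[[p]]) {
      if (vertex_of[q] != 0L && vertex_of[q] == vertex_of[p]) next
      if (exists(ekey(p, q), envir = used)) next
      path <- trace_from(p, q)
      last <- path[length(path)]
      if (vertex_of[last] == 0L) next
      v1 <- vertex_of[p]; v2 <- vertex_of[last]
      inner <- path[vertex_of[path] == 0L]
      pts <- rbind(c(vx[[v1]], vy[[v1]]),
                   coord[inner, , drop = FALSE],
                   c(vx[[v2]], vy[[v2]]))
      if (v1 == v2 && length(inner) < 3) next  # degenerate junction micro-loop
      add_wall(v1, v2, pts)
    }
  }
  # pure cycles: components made only of degree-2 pixels
  remaining <- which(vertex_of == 0L &
                       !vapply(seq_len(nrow(pix)), function(p)
                         any(vapply(adj[[p]], function(q)
                           exists(ekey(p, q), envir = used), logical(1))),
                         logical(1)) & deg == 2)
  while (length(remaining)) {
    start <- remaining[1]
    nv <- nv + 1L
    vx[[nv]] <- coord[start, 1]; vy[[nv]] <- coord[start, 2]
    vertex_of[start] <- nv
    path <- trace_from(start, adj[[start]][1])
    inner <- path[vertex_of[path] == 0L]
    pts <- rbind(coord[start, , drop = FALSE],
                 coord[inner, , drop = FALSE],
                 coord[start, , drop = FALSE])
    add_wall(nv, nv, pts)
    remaining <- setdiff(remaining, path)
  }

  g <- new_wall_graph(data.frame(x = unlist(vx), y = unlist(vy)), walls,
                      unit = "px", scale = scale)
  if (!is.null(scale)) g <- graph_to_um(g, scale) else g
}

#' Prune short dangling spurs from a wall graph
#'
#' Voronoi wall extraction occasionally leaves short triangular branches
#' dangling off a real wall. This removes them automatically: walls with a
#' degree-1 endpoint and length below `max_len` are deleted iteratively
#' until none remain, and degree-2 vertices created by a deletion are
#' dissolved (their two walls merged into one polyline).
#'
#' @param g a `wall_graph`.
#' @param max_len maximum spur length to delete, in graph units (um for a
#'   calibrated graph; default 5).
#' @return pruned `wall_graph`.
#' @export
prune_spurs <- function(g, max_len = 5) {
  repeat {
    if (length(g$walls) == 0) break
    degs <- vertex_degrees(g)
    lens <- wall_lengths(g)
    spur <- vapply(seq_along(g$walls), function(i) {
      w <- g$walls[[i]]
      (degs[w$v[1]] == 1 || degs[w$v[2]] == 1) && lens[i] < max_len &&
        w$v[1] != w$v[2]
    }, logical(1))
    if (!any(spur)) break
    g$walls <- g$walls[!spur]
    g <- dissolve_degree2(g)
  }
  drop_isolated_vertices(g)
}

# degree of each vertex (a closed loop contributes 2 to its vertex)
vertex_degrees <- function(g) {
  degs <- integer(nrow(g$vertices))
  for (w in g$walls) {
    degs[w$v[1]] <- degs[w$v[1]] + 1L
    degs[w$v[2]] <- degs[w$v[2]] + 1L
  }
  degs
}

# merge the two walls at every degree-2 vertex (skipping loops)
dissolve_degree2 <- function(g) {
  repeat {
    degs <- vertex_degrees(g)
    incid <- lapply(seq_len(nrow(g$vertices)), function(v)
      which(vapply(g$walls, function(w) any(w$v == v), logical(1))))
    v2 <- which(degs == 2 & lengths(incid) == 2)
    if (!length(v2)) return(g)
    v <- v2[1]
    ids <- incid[[v]]
    w1 <- g$walls[[ids[1]]]; w2 <- g$walls[[ids[2]]]
    p1 <- if (w1$v[2] == v) w1$points else w1$points[nrow(w1$points):1, ]
    a1 <- if (w1$v[2] == v) w1$v[1] else w1$v[2]
    p2 <- if (w2$v[1] == v) w2$points else w2$points[nrow(w2$points):1, ]
    a2 <- if (w2$v[1] == v) w2$v[2] else w2$v[1]
    l1 <- polyline_length(w1$points); l2 <- polyline_length(w2$points)
    th <- if (is.na(w1$thickness) && is.na(w2$thickness)) NA_real_
          else stats::weighted.mean(c(w1$thickness, w2$thickness),
                                    c(l1, l2), na.rm = TRUE)
    merged <- list(v = c(a1, a2),
                   points = rbind(p1, p2[-1, , drop = FALSE]),
                   thickness = th)
    g$walls <- c(g$walls[-ids], list(merged))
  }
}

# drop vertices no wall references, renumbering wall endpoints
drop_isolated_vertices <- function(g) {
  keep <- sort(unique(unlist(lapply(g$walls, function(w) w$v))))
  if (length(keep) == nrow(g$vertices)) return(g)
  map <- integer(nrow(g$vertices))
  map[keep] <- seq_along(keep)
  g$vertices <- g$vertices[keep, , drop = FALSE]
  rownames(g$vertices) <- NULL
  g$walls <- lapply(g$walls, function(w) { w$v <- map[w$v]; w })
  g
}

# internal: strip label_map class for arithmetic
unclass_label <- function(x) {
  x <- unclass(x)
  attr(x, "border_touching") <- NULL
  storage.mode(x) <- "integer"
  x
}
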