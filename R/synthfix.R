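#' Regular honeycomb wall graph with ground truth
#'
#' Generates a rows x cols tiling of regular hexagonal cells (pointy-top
#' orientation: each cell has two vertical walls, the configuration whose
#' in-plane modulus under horizontal load has the classical closed form,
#' see [gibson_ashby_modulus()]). Shared vertices are merged, all walls
#' carry thickness `wall_thickness`, and optional seeded jitter displaces
#' each vertex uniformly by up to `jitter * edge_len` per coordinate while
#' preserving the topology. The result emulates parenchyma-like tissue with
#' exact ground truth.
#'
#' @param rows,cols cell counts (>= 1).
#' @param edge_len hexagon edge length l, um (default 60, giving
#'   `t/l ~ 0.07` at the default thickness -- the regime of stained maize
#'   parenchyma micrographs).
#' @param wall_thickness wall thickness t, um (default 4.3).
#' @param jitter vertex jitter as a fraction of l, in `[0, 0.3)`.
#' @param seed integer seed for the jitter.
#' @return a `wall_graph` in um whose `truth` field holds `n_cells`,
#'   `centers` (cell centers) and `polygons` (list of 6 x 2 vertex
#'   coordinate matrices per cell).
#' @examples
#' g <- honeycomb_graph(3, 4, edge_len = 20)
#' g$truth$n_cells  # 12
#' @export
honeycomb_graph <- function(rows, cols, edge_len = 60, wall_thickness = 4.3,
                            jitter = 0, seed = 1L) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  if (jitter < 0 || jitter >= 0.3) stop("jitter must be in [0, 0.3)")
  if (edge_len <= 0) stop("edge_len must be > 0")
  l <- edge_len
  ang <- (c(90, 150, 210, 270, 330, 30)) * pi / 180
  hx <- l * cos(ang); hy <- l * sin(ang)
  centers <- expand.grid(c = seq_len(cols) - 1, r = seq_len(rows) - 1)
  cx <- sqrt(3) * l * (centers$c + 0.5 * (centers$r %% 2))
  cy <- 1.5 * l * centers$r
  n_cells <- rows * cols

  # merge shared vertices on a rounded-coordinate key
  keyf <- function(x, y) paste(round(x / l, 6), round(y / l, 6))
  vmap <- new.env(hash = TRUE)
  vx <- numeric(0); vy <- numeric(0)
  cell_vid <- matrix(0L, n_cells, 6)
  for (k in seq_len(n_cells)) {
    for (m in 1:6) {
      x <- cx[k] + hx[m]; y <- cy[k] + hy[m]
      key <- keyf(x, y)
      id <- vmap[[key]]
      if (is.null(id)) {
        vx <- c(vx, x); vy <- c(vy, y)
        id <- length(vx)
        vmap[[key]] <- id
      }
      cell_vid[k, m] <- id
    }
  }
  if (jitter > 0) {
    set.seed(seed)
    vx <- vx + stats::runif(length(vx), -jitter * l, jitter * l)
    vy <- vy + stats::runif(length(vy), -jitter * l, jitter * l)
  }
  # unique undirected edges
  e1 <- as.vector(cell_vid)
  e2 <- as.vector(cell_vid[, c(2:6, 1)])
  ekey <- paste(pmin(e1, e2), pmax(e1, e2))
  keep <- !duplicated(ekey)
  e1 <- e1[keep]; e2 <- e2[keep]
  walls <- lapply(seq_along(e1), function(i) list(
    v = c(e1[i], e2[i]),
    points = rbind(c(vx[e1[i]], vy[e1[i]]), c(vx[e2[i]], vy[e2[i]])),
    thickness = wall_thickness))
  g <- new_wall_graph(data.frame(x = vx, y = vy), walls, unit = "um",
                      scale = NULL)
  g$truth <- list(
    n_cells = n_cells,
    centers = cbind(x = cx, y = cy),
    polygons = lapply(seq_len(n_cells), function(k)
      cbind(vx[cell_vid[k, ]], vy[cell_vid[k, ]])))
  g
}

#' Render a synthetic micrograph from a wall graph
#'
#' Rasterizes a honeycomb wall graph into a brightfield-like image: dark
#' walls of finite pixel width on bright cell interiors, with optional
#' additive Gaussian noise and speckle (a fraction of pixels replaced by
#' uniform random intensities), all seeded for bit reproducibility. The
#' frame outside the tiled cells is rendered at wall intensity so that the
#' ground-truth cells are exactly the bright interior regions.
#'
#' @param g a honeycomb `wall_graph` from [honeycomb_graph()] (needs its
#'   `truth` polygons).
#' @param px_per_um raster resolution (default 2).
#' @param wall_px rendered wall width in pixels (default 3).
#' @param interior_intensity,wall_intensity 8-bit intensities; interiors
#'   must be brighter than walls (default 200 and 40).
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param speckle_fraction fraction of pixels replaced by uniform noise.
#' @param seed integer seed.
#' @return list with `image` (a [raster_image()], scale `1/px_per_um`) and
#'   `truth` (ground-truth `label_map`; 0 = wall/outside).
#' @export
render_image <- function(g, px_per_um = 2, wall_px = 3,
                         interior_intensity = 200, wall_intensity = 40,
                         noise_sigma = 0, speckle_fraction = 0, seed = 1L) {
  stopifnot(inherits(g, "wall_graph"), !is.null(g$truth))
  if (interior_intensity <= wall_intensity)
    stop("interiors must be brighter than walls")
  if (wall_px < 1) stop("wall_px must be >= 1")
  xr <- range(g$vertices$x); yr <- range(g$vertices$y)
  nc <- ceiling((xr[2] - xr[1]) * px_per_um)
  nr <- ceiling((yr[2] - yr[1]) * px_per_um)
  # pixel-center coordinates in um
  xs <- xr[1] + (seq_len(nc) - 0.5) / px_per_um
  ys <- yr[2] - (seq_len(nr) - 0.5) / px_per_um
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)

  halfw <- wall_px / (2 * px_per_um)
  wall <- matrix(FALSE, nr, nc)
  for (w in g$walls) {
    for (s in seq_len(nrow(w$points) - 1)) {
      a <- w$points[s, ]; b <- w$points[s + 1, ]
      lo_c <- max(1L, floor((min(a[1], b[1]) - halfw - xr[1]) * px_per_um))
      hi_c <- min(nc, ceiling((max(a[1], b[1]) + halfw - xr[1]) * px_per_um) + 1L)
      lo_r <- max(1L, floor((yr[2] - max(a[2], b[2]) - halfw) * px_per_um))
      hi_r <- min(nr, ceiling((yr[2] - min(a[2], b[2]) + halfw) * px_per_um) + 1L)
      if (lo_c > hi_c || lo_r > hi_r) next
      rs <- lo_r:hi_r; cs <- lo_c:hi_c
      d <- point_segment_dist(X[rs, cs, drop = FALSE],
                              Y[rs, cs, drop = FALSE], a, b)
      wall[rs, cs] <- wall[rs, cs] | (d <= halfw)
    }
  }

  truth <- matrix(0L, nr, nc)
  for (k in seq_len(g$truth$n_cells)) {
    poly <- g$truth$polygons[[k]]
    lo_c <- max(1L, floor((min(poly[, 1]) - xr[1]) * px_per_um))
    hi_c <- min(nc, ceiling((max(poly[, 1]) - xr[1]) * px_per_um) + 1L)
    lo_r <- max(1L, floor((yr[2] - max(poly[, 2])) * px_per_um))
    hi_r <- min(nr, ceiling((yr[2] - min(poly[, 2])) * px_per_um) + 1L)
    rs <- lo_r:hi_r; cs <- lo_c:hi_c
    inside <- point_in_polygon(X[rs, cs, drop = FALSE],
                               Y[rs, cs, drop = FALSE], poly)
    sub <- truth[rs, cs, drop = FALSE]
    sub[inside & sub == 0L] <- k
    truth[rs, cs] <- sub
  }
  outside <- truth == 0L & !wall
  truth[wall] <- 0L

  img <- matrix(interior_intensity, nr, nc)
  img[wall | outside] <- wall_intensity
  set.seed(seed)
  if (noise_sigma > 0)
    img <- img + stats::rnorm(length(img), 0, noise_sigma)
  if (speckle_fraction > 0) {
    n_spk <- round(speckle_fraction * length(img))
    at <- sample.int(length(img), n_spk)
    img[at] <- stats::runif(n_spk, 0, 255)
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = raster_image(img, 8L, scale = 1 / px_per_um),
       truth = structure(truth, class = c("label_map", "matrix")))
}

# distance of grid points (Xm, Ym) to segment a-b
point_segment_dist <- function(Xm, Ym, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  if (len2 == 0) return(sqrt((Xm - a[1])^2 + (Ym - a[2])^2))
  t <- ((Xm - a[1]) * abx + (Ym - a[2]) * aby) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((Xm - (a[1] + t * abx))^2 + (Ym - (a[2] + t * aby))^2)
}

# even-odd rule point-in-polygon for grid points
point_in_polygon <- function(Xm, Ym, poly) {
  n <- nrow(poly)
  inside <- matrix(FALSE, nrow(Xm), ncol(Xm))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > Ym) != (yj > Ym)) &
      (Xm < (xj - xi) * (Ym - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Gibson-Ashby in-plane modulus of a regular honeycomb
#'
#' Closed-form effective elastic modulus of a regular hexagonal honeycomb
#' of wall thickness `t` and edge length `l` loaded in-plane:
#' `E* = E_s (t/l)^3 cos(theta) / ((h/l + sin(theta)) sin(theta)^2)` with
#' `theta = 30` degrees and `h = l`, i.e. `E* = (4 / sqrt(3)) E_s (t/l)^3`.
#' Valid in the thin-wall (bending-dominated) regime `t << l`; used as an
#' independent oracle for the beam solver.
#'
#' @param E_s wall material modulus.
#' @param t wall thickness, um.
#' @param l edge length, um (must exceed `t`).
#' @return effective modulus, same units as `E_s`.
#' @examples
#' gibson_ashby_modulus(1, 0.1, 1)  # 4/sqrt(3) * 1e-3
#' @export
gibson_ashby_modulus <- function(E_s, t, l) {
  if (t >= l) stop("thick-wall regime: oracle requires t < l")
  E_s * (t / l)^3 * 4 / sqrt(3)
}

#' Homogenized modulus of a solved tension test
#'
#' Converts a structural stiffness from [structural_stiffness()] into an
#' effective modulus via `E_eff = K * W / (H * depth)` where `W` is the
#' specimen extent along the stretch direction and `H` its transverse
#' extent.
#'
#' @param mesh the `fe_mesh` (um coordinates).
#' @param K structural stiffness.
#' @param direction `"x"` (right-stretch) or `"y"` (top-stretch).
#' @return effective modulus in the units of E.
#' @export
homogenized_modulus <- function(mesh, K, direction = c("x", "y")) {
  direction <- match.arg(direction)
  W <- diff(range(mesh$nodes[, 1]))
  H <- diff(range(mesh$nodes[, 2]))
  if (direction == "x") K * W / (H * mesh$depth) else K * H / (W * mesh$depth)
}
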