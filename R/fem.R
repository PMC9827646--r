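#' Rectangular beam section properties
#'
#' Cross-section constants of a rectangular cell-wall section of thickness
#' `t` (in-plane) and out-of-plane `depth`: area `A = t * depth`, second
#' moment `I = depth * t^3 / 12`, and shear area `A_s = kappa * A` with the
#' rectangular shear factor `kappa = 5/6`. Under the plane-stress
#' idealization the default depth is 1 um, so stiffnesses are per unit
#' depth.
#'
#' @param t wall thickness, um (> 0).
#' @param depth out-of-plane depth, um (> 0, default 1).
#' @return list with `A`, `I`, `As` (and `t`, `depth`).
#' @examples
#' section_properties(4.3)  # A = 4.3, I = 4.3^3/12
#' @export
section_properties <- function(t, depth = 1) {
  if (any(t <= 0) || any(depth <= 0)) stop("section dimensions must be > 0")
  list(t = t, depth = depth, A = t * depth, I = depth * t^3 / 12,
       As = 5 / 6 * t * depth)
}

#' Mesh a wall graph with 2-node beam elements
#'
#' Subdivides every wall polyline into `ceil(length / seed_size)` elements
#' of equal arc length along the polyline, the beam analogue of meshing
#' with a 1 um seed. Wall endpoints share the graph's junction nodes, so
#' elements of different walls are rigidly connected there. Each element
#' inherits its wall's thickness; walls without one get `default_thickness`.
#'
#' @param g a `wall_graph` in um (a pixel-unit graph with a known scale is
#'   converted; otherwise an error is signaled).
#' @param seed_size target element length, um (default 1).
#' @param default_thickness thickness for walls lacking one (um, default
#'   4.3, a literature average for maize parenchyma walls).
#' @param depth out-of-plane section depth, um (default 1).
#' @return an object of class `fe_mesh`: `nodes` (n x 2 um), `elements`
#'   (data frame `n1`, `n2`, `wall`, `thickness`), `seed_size`, `depth`.
#' @export
graph_to_mesh <- function(g, seed_size = 1, default_thickness = 4.3,
                          depth = 1) {
  stopifnot(inherits(g, "wall_graph"))
  if (g$unit == "px") {
    if (is.null(g$scale)) stop("uncalibrated geometry: convert to um first")
    g <- graph_to_um(g)
  }
  if (seed_size <= 0) stop("seed_size must be > 0")
  nodes <- as.matrix(g$vertices[, c("x", "y")])
  el <- list()
  for (wi in seq_along(g$walls)) {
    w <- g$walls[[wi]]
    th <- if (is.null(w$thickness) || is.na(w$thickness)) default_thickness
          else w$thickness
    L <- polyline_length(w$points)
    n <- max(1L, ceiling(L / seed_size))
    s <- seq(0, L, length.out = n + 1)
    ptsx <- interp_polyline(w$points, s)
    ids <- integer(n + 1)
    ids[1] <- w$v[1]; ids[n + 1] <- w$v[2]
    if (n > 1) {
      newid <- nrow(nodes) + seq_len(n - 1)
      nodes <- rbind(nodes, ptsx[2:n, , drop = FALSE])
      ids[2:n] <- newid
    }
    el[[wi]] <- data.frame(n1 = ids[-(n + 1)], n2 = ids[-1],
                           wall = wi, thickness = th)
  }
  elements <- do.call(rbind, el)
  len <- sqrt(rowSums((nodes[elements$n2, , drop = FALSE] -
                         nodes[elements$n1, , drop = FALSE])^2))
  if (any(len <= 0)) stop("zero-length element produced by meshing")
  structure(list(nodes = unname(nodes), elements = elements,
                 seed_size = seed_size, depth = depth),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d B21-type beam elements, seed %.3g um\n",
              nrow(x$nodes), nrow(x$elements), x$seed_size))
  invisible(x)
}

# sample a polyline at arc lengths s (vector), returning length(s) x 2
interp_polyline <- function(pts, s) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  s <- pmin(pmax(s, 0), tot)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
            length(seg))
  frac <- ifelse(seg[i] > 0, (s - cum[i]) / seg[i], 0)
  pts[i, , drop = FALSE] + (pts[i + 1, , drop = FALSE] -
                              pts[i, , drop = FALSE]) * frac
}

#' Construct an explicit boundary-condition set
#'
#' Low-level constructor for non-preset load cases (patch tests, single
#' cantilevers, custom platens). DOF numbering: 1 = x translation, 2 = y
#' translation, 3 = rotation.
#'
#' @param fixed data frame with columns `node`, `dof` (held at zero).
#' @param prescribed data frame with columns `node`, `dof`, `value`
#'   (displacement-driven DOFs, um).
#' @param stretch the nominal stretch used to normalize
#'   [structural_stiffness()]; defaults to the first prescribed value.
#' @return a `bc_spec`.
#' @export
bc_spec <- function(fixed, prescribed, stretch = prescribed$value[1]) {
  fixed <- as.data.frame(fixed)
  prescribed <- as.data.frame(prescribed)
  key <- function(df) paste(df$node, df$dof)
  if (any(key(fixed) %in% key(prescribed)))
    stop("a DOF cannot be both fixed and prescribed")
  if (nrow(fixed) + nrow(prescribed) < 3)
    stop("degenerate BCs: fewer than 3 constrained DOFs")
  structure(list(preset = "custom", fixed = fixed, prescribed = prescribed,
                 stretch = stretch, band = NA_real_),
            class = "bc_spec")
}

#' Boundary-condition presets
#'
#' Builds the boundary conditions of the virtual tension test. Nodes are
#' selected by coordinate bands of half-width `band` (default
#' `seed_size / 2`) at the extremes of the mesh.
#'
#' * `right_stretch` (the sensitivity-study test): nodes at the left edge
#'   are fixed in x, the lowest of them is additionally fixed in y, and
#'   nodes at the right edge are displaced by `+stretch` um in x.
#' * `top_stretch`: bottom nodes fixed in y, leftmost and rightmost nodes
#'   fixed in x, top nodes displaced by `+stretch` um in y.
#'
#' Rotations are never constrained.
#'
#' @param mesh an `fe_mesh`.
#' @param preset `"right_stretch"` or `"top_stretch"`.
#' @param stretch prescribed displacement, um (default 1).
#' @param band node-selection tolerance, um.
#' @return an object of class `bc_spec` with data frames `fixed`
#'   (`node`, `dof`) and `prescribed` (`node`, `dof`, `value`); dof 1 = x,
#'   2 = y, 3 = rotation.
#' @export
apply_bcs <- function(mesh, preset = c("right_stretch", "top_stretch"),
                      stretch = 1, band = mesh$seed_size / 2) {
  preset <- match.arg(preset)
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  near <- function(v, target) which(abs(v - target) <= band)
  if (preset == "right_stretch") {
    left <- near(x, min(x)); right <- near(x, max(x))
    fixed <- data.frame(node = left, dof = 1L)
    anchor <- left[order(y[left], x[left])][1]
    fixed <- rbind(fixed, data.frame(node = anchor, dof = 2L))
    prescribed <- data.frame(node = right, dof = 1L, value = stretch)
  } else {
    bottom <- near(y, min(y)); top <- near(y, max(y))
    left <- near(x, min(x)); right <- near(x, max(x))
    fixed <- rbind(data.frame(node = bottom, dof = 2L),
                   data.frame(node = c(left, right), dof = 1L))
    prescribed <- data.frame(node = top, dof = 2L, value = stretch)
  }
  # a node both fixed and driven on the same dof would be contradictory
  key <- function(df) paste(df$node, df$dof)
  fixed <- fixed[!key(fixed) %in% key(prescribed), , drop = FALSE]
  if (nrow(prescribed) == 0) stop("degenerate BCs: empty driven node set")
  if (nrow(fixed) + nrow(prescribed) < 3)
    stop("degenerate BCs: fewer than 3 constrained DOFs")
  structure(list(preset = preset, fixed = fixed, prescribed = prescribed,
                 stretch = stretch, band = band),
            class = "bc_spec")
}

#' Solve the 2D beam-network model
#'
#' Linear small-displacement solution of the wall network as a 2D
#' Timoshenko (shear-flexible) frame, the element formulation matching
#' 2-node linear B21 beams: 3 DOF per node (two translations and a
#' rotation), per-element shear parameter `Phi = 12 E I / (kappa G A L^2)`
#' with `G = E / (2 (1 + nu))`, sparse assembly, elimination of prescribed
#' DOFs and a direct solve. Displacements of order 1 um over specimens of
#' order 100 um keep the response effectively linear, so no geometric
#' nonlinearity is carried.
#'
#' @param mesh an `fe_mesh`.
#' @param mat material, `list(E =, nu =)`; E in force/um^2 (consistent
#'   units; default `E = 1`, `nu = 0.3` -- normalized sensitivities do not
#'   depend on it).
#' @param bcs a `bc_spec` from [apply_bcs()].
#' @return an object of class `fe_result`: `u` (all DOF displacements),
#'   `reactions` (data frame `node`, `dof`, `value` at constrained DOFs),
#'   `end_forces` (per element: `N1`, `V1`, `M1`, `N2`, `V2`, `M2` in local
#'   axes), plus the mesh and material for downstream stress recovery.
#' @export
solve_frame <- function(mesh, mat = list(E = 1, nu = 0.3), bcs) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(bcs, "bc_spec"))
  E <- mat$E; nu <- mat$nu
  if (is.null(E) || E <= 0) stop("material needs E > 0")
  if (is.null(nu) || nu <= -1 || nu >= 0.5) stop("nu must be in (-1, 0.5)")
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  ndof <- 3L * nn
  G <- E / (2 * (1 + nu))

  n1 <- mesh$elements$n1; n2 <- mesh$elements$n2
  dx <- mesh$nodes[n2, 1] - mesh$nodes[n1, 1]
  dy <- mesh$nodes[n2, 2] - mesh$nodes[n1, 2]
  L <- sqrt(dx^2 + dy^2)
  cth <- dx / L; sth <- dy / L
  sec <- section_properties(mesh$elements$thickness, mesh$depth)
  A <- sec$A; I <- sec$I; As <- sec$As
  Phi <- 12 * E * I / (G * As * L^2)

  # local stiffness entries (6x6, symmetric), frame (u1 v1 th1 u2 v2 th2)
  ka <- E * A / L
  kb <- E * I / ((1 + Phi) * L^3)
  k11 <- 12 * kb; k12 <- 6 * kb * L
  k22 <- (4 + Phi) * kb * L^2; k22b <- (2 - Phi) * kb * L^2

  trip_i <- vector("list", ne); trip_j <- vector("list", ne)
  trip_x <- vector("list", ne)
  kloc_all <- vector("list", ne)
  for (e in seq_len(ne)) {
    kl <- matrix(0, 6, 6)
    kl[1, 1] <- kl[4, 4] <- ka[e]; kl[1, 4] <- kl[4, 1] <- -ka[e]
    kl[2, 2] <- kl[5, 5] <- k11[e]; kl[2, 5] <- kl[5, 2] <- -k11[e]
    kl[2, 3] <- kl[3, 2] <- kl[2, 6] <- kl[6, 2] <- k12[e]
    kl[5, 3] <- kl[3, 5] <- kl[5, 6] <- kl[6, 5] <- -k12[e]
    kl[3, 3] <- kl[6, 6] <- k22[e]
    kl[3, 6] <- kl[6, 3] <- k22b[e]
    c1 <- cth[e]; s1 <- sth[e]
    R <- matrix(0, 6, 6)
    R[1, 1] <- R[2, 2] <- R[4, 4] <- R[5, 5] <- c1
    R[1, 2] <- R[4, 5] <- s1
    R[2, 1] <- R[5, 4] <- -s1
    R[3, 3] <- R[6, 6] <- 1
    kg <- t(R) %*% kl %*% R
    dofs <- c(3 * n1[e] - 2, 3 * n1[e] - 1, 3 * n1[e],
              3 * n2[e] - 2, 3 * n2[e] - 1, 3 * n2[e])
    trip_i[[e]] <- rep(dofs, times = 6)
    trip_j[[e]] <- rep(dofs, each = 6)
    trip_x[[e]] <- as.vector(kg)
    kloc_all[[e]] <- kl
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(ndof, ndof))

  dof_id <- function(df) 3L * (df$node - 1L) + df$dof
  c_fix <- dof_id(bcs$fixed)
  c_pre <- dof_id(bcs$prescribed)
  cons <- c(c_fix, c_pre)
  if (anyDuplicated(cons)) stop("a DOF is both fixed and prescribed")
  uc <- c(rep(0, length(c_fix)), bcs$prescribed$value)
  free <- setdiff(seq_len(ndof), cons)

  u <- numeric(ndof)
  u[cons] <- uc
  rhs <- -K[free, cons, drop = FALSE] %*% uc
  Kff <- K[free, free, drop = FALSE]
  # sparse Cholesky (the constrained frame stiffness is SPD) with one step
  # of iterative refinement; slender-wall networks are ill-conditioned and
  # the refinement recovers near machine-precision reactions
  fac <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                  error = function(e) NULL)
  solve_ff <- function(b) {
    if (!is.null(fac)) Matrix::solve(fac, b, system = "A")
    else Matrix::solve(Kff, b)
  }
  uf <- tryCatch({
    u0 <- solve_ff(rhs)
    u0 + solve_ff(rhs - Kff %*% u0)
  }, error = function(e)
    stop("singular system: under-constrained or ",
         "disconnected geometry (", conditionMessage(e), ")"))
  u[free] <- as.numeric(uf)

  r_all <- as.numeric(K %*% u)
  reactions <- data.frame(
    node = c(bcs$fixed$node, bcs$prescribed$node),
    dof = c(bcs$fixed$dof, bcs$prescribed$dof),
    value = r_all[cons])

  # local end forces: f = k_loc (R u_e)
  ef <- matrix(0, ne, 6)
  for (e in seq_len(ne)) {
    dofs <- c(3 * n1[e] - 2, 3 * n1[e] - 1, 3 * n1[e],
              3 * n2[e] - 2, 3 * n2[e] - 1, 3 * n2[e])
    ue <- u[dofs]
    c1 <- cth[e]; s1 <- sth[e]
    ul <- c(c1 * ue[1] + s1 * ue[2], -s1 * ue[1] + c1 * ue[2], ue[3],
            c1 * ue[4] + s1 * ue[5], -s1 * ue[4] + c1 * ue[5], ue[6])
    ef[e, ] <- as.numeric(kloc_all[[e]] %*% ul)
  }
  end_forces <- data.frame(N1 = ef[, 1], V1 = ef[, 2], M1 = ef[, 3],
                           N2 = ef[, 4], V2 = ef[, 5], M2 = ef[, 6])

  structure(list(u = u, reactions = reactions, end_forces = end_forces,
                 mesh = mesh, material = mat, element_length = L),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("<fe_result> %d DOF solved, %d constrained\n",
              length(x$u), nrow(x$reactions)))
  invisible(x)
}

#' Structural stiffness from a solved model
#'
#' The virtual tension test's stiffness: the total reaction force in the
#' stretch direction over the displacement-driven nodes, divided by the
#' prescribed stretch. Units: force per um of stretch (per unit out-of-plane
#' depth with the default section depth).
#'
#' @param res an `fe_result`.
#' @param bcs the `bc_spec` used to solve.
#' @return stiffness K (> 0 for a connected constrained structure).
#' @export
structural_stiffness <- function(res, bcs) {
  stopifnot(inherits(res, "fe_result"), inherits(bcs, "bc_spec"))
  key <- paste(res$reactions$node, res$reactions$dof)
  drv <- paste(bcs$prescribed$node, bcs$prescribed$dof)
  sum(res$reactions$value[key %in% drv]) / bcs$stretch
}

#' Per-element von Mises stress
#'
#' Beam-theory stress recovery at both element ends: axial-plus-bending
#' fiber stress `sigma = N/A +/- M (t/2) / I` at both extreme fibers,
#' transverse shear `tau = V / A_s`, combined as
#' `sigma_vm = sqrt(sigma^2 + 3 tau^2)`; the element value is the maximum
#' over ends and fibers.
#'
#' @param res an `fe_result`.
#' @return numeric vector, one stress per element (force/um^2 units of E).
#' @export
element_von_mises <- function(res) {
  stopifnot(inherits(res, "fe_result"))
  sec <- section_properties(res$mesh$elements$thickness, res$mesh$depth)
  ef <- res$end_forces
  vm_end <- function(N, V, M) {
    s_ax <- abs(N) / sec$A + abs(M) * (sec$t / 2) / sec$I
    tau <- abs(V) / sec$As
    sqrt(s_ax^2 + 3 * tau^2)
  }
  pmax(vm_end(ef$N1, ef$V1, ef$M1), vm_end(ef$N2, ef$V2, ef$M2))
}

#' Table-average wall thickness
#'
#' Arithmetic mean of nominal literature thickness values, reported to one
#' decimal -- e.g. the published maize values 3.7, 6.8, 2.0 and 4.6 um
#' average to 4.3 um.
#'
#' @param nominals numeric vector of nominal thicknesses, um.
#' @return mean thickness rounded to one decimal.
#' @export
average_thickness <- function(nominals) {
  if (length(nominals) < 1) stop("empty thickness list")
  round(mean(nominals), 1)
}

#' Overlay element stresses on a micrograph
#'
#' Draws the beam elements over the original image, colored from blue
#' (minimum stress) to red (maximum) by linear normalization. With a
#' degenerate range (uniform stress) all elements render blue.
#'
#' @param img a [raster_image()] (grayscale background).
#' @param mesh the `fe_mesh` (um coordinates).
#' @param stresses per-element values, e.g. from [element_von_mises()].
#' @param scale um per pixel relating mesh coordinates to the image.
#' @return `H x W x 3` RGB array on `[0, 255]`.
#' @export
overlay_stress <- function(img, mesh, stresses, scale = img$scale) {
  stopifnot(inherits(img, "raster_image"), inherits(mesh, "fe_mesh"))
  if (is.null(scale)) stop("scale required to map um onto pixels")
  p <- img$pixels * (255 / (2^img$bit_depth - 1))
  nr <- nrow(p); nc <- ncol(p)
  out <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) out[, , ch] <- p
  rng <- range(stresses)
  f <- if (rng[2] > rng[1]) (stresses - rng[1]) / (rng[2] - rng[1])
       else rep(0, length(stresses))
  cols <- grDevices::colorRamp(c("blue", "red"))(f)
  to_rc <- function(xy) cbind(row = nr - xy[, 2] / scale + 1,
                              col = xy[, 1] / scale)
  for (e in seq_len(nrow(mesh$elements))) {
    a <- mesh$nodes[mesh$elements$n1[e], ]
    b <- mesh$nodes[mesh$elements$n2[e], ]
    rc <- to_rc(rbind(a, b))
    pts <- bresenham(rc[1, 1], rc[1, 2], rc[2, 1], rc[2, 2])
    ok <- pts[, 1] >= 1 & pts[, 1] <= nr & pts[, 2] >= 1 & pts[, 2] <= nc
    pts <- pts[ok, , drop = FALSE]
    for (ch in 1:3) out[cbind(pts, ch)] <- cols[e, ch]
  }
  out
}

# integer line rasterization between two (row, col) points
bresenham <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  cbind(round(seq(r0, r1, length.out = n)),
        round(seq(c0, c1, length.out = n)))
}
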