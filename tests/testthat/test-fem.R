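test_that("section_properties follows the rectangular closed forms", {
  s <- section_properties(4.3, 1)
  expect_equal(s$A, 4.3)
  expect_equal(s$I, 4.3^3 / 12)
  expect_equal(s$As, 5 / 6 * 4.3)
  expect_equal(section_properties(2 * 4.3, 1)$I / s$I, 8)   # cubic law
  s2 <- section_properties(1, 2)
  expect_equal(s2$A, 2)
  expect_equal(s2$I, 1 / 6)
  expect_error(section_properties(0, 1), "must be > 0")
})

test_that("graph_to_mesh subdivides walls by the ceil rule and shares joints", {
  g <- bar_graph(L = 10, t = 2)
  mesh <- graph_to_mesh(g, seed_size = 1)
  expect_equal(nrow(mesh$elements), 10)
  expect_equal(nrow(mesh$nodes), 11)

  g2 <- bar_graph(L = 10.4, t = 2)
  mesh2 <- graph_to_mesh(g2, seed_size = 1)
  expect_equal(nrow(mesh2$elements), 11)
  len <- sqrt(rowSums((mesh2$nodes[mesh2$elements$n2, ] -
                         mesh2$nodes[mesh2$elements$n1, ])^2))
  expect_equal(len, rep(10.4 / 11, 11), tolerance = 1e-12)

  # T graph: center vertex shared by elements of all three walls
  v <- data.frame(x = c(0, 10, 20, 10), y = c(0, 0, 0, -10))
  mk <- function(a, b) list(v = c(a, b),
                            points = as.matrix(rbind(v[a, ], v[b, ])),
                            thickness = 2)
  gt <- new_wall_graph(v, list(mk(1, 2), mk(2, 3), mk(2, 4)), unit = "um")
  mt <- graph_to_mesh(gt, seed_size = 1)
  touching <- sum(mt$elements$n1 == 2 | mt$elements$n2 == 2)
  expect_equal(touching, 3)
  expect_equal(sort(unique(mt$elements$wall[mt$elements$n1 == 2 |
                                              mt$elements$n2 == 2])), 1:3)

  gpx <- new_wall_graph(data.frame(x = c(0, 5), y = c(0, 0)),
                        list(list(v = c(1L, 2L),
                                  points = rbind(c(0, 0), c(5, 0)),
                                  thickness = 1)), unit = "px")
  expect_error(graph_to_mesh(gpx), "uncalibrated")
})

test_that("axial patch test recovers EA delta / L to machine precision", {
  mesh <- graph_to_mesh(bar_graph(L = 10, t = 2), seed_size = 1)
  bcs <- bar_axial_bcs(mesh, stretch = 0.1)
  mat <- list(E = 3, nu = 0.3)
  res <- solve_frame(mesh, mat, bcs)
  K <- structural_stiffness(res, bcs)
  EA_L <- 3 * 2 / 10
  expect_equal(K, EA_L, tolerance = 1e-9)
  # pure axial state: zero moments and shears everywhere
  expect_true(all(abs(res$end_forces$M1) < 1e-12))
  expect_true(all(abs(res$end_forces$V2) < 1e-12))
  # equilibrium
  rx <- sum(res$reactions$value[res$reactions$dof == 1])
  expect_lt(abs(rx) / max(abs(res$reactions$value)), 1e-10)
})

test_that("cantilever tip stiffness matches the Timoshenko closed form", {
  L <- 12; t <- 1.5; E <- 2; nu <- 0.3
  mesh <- graph_to_mesh(bar_graph(L = L, t = t), seed_size = 0.5)
  left <- which(mesh$nodes[, 1] == 0)
  tip <- which(mesh$nodes[, 1] == L)
  bcs <- bc_spec(fixed = data.frame(node = rep(left, 3), dof = 1:3),
                 prescribed = data.frame(node = tip, dof = 2, value = 0.01))
  res <- solve_frame(mesh, list(E = E, nu = nu), bcs)
  P <- sum(res$reactions$value[res$reactions$node == tip &
                                 res$reactions$dof == 2])
  sec <- section_properties(t, 1)
  G <- E / (2 * (1 + nu))
  delta_per_P <- L^3 / (3 * E * sec$I) + L / (G * sec$As)
  expect_equal(0.01 / P, delta_per_P, tolerance = 1e-9)
})

test_that("stiffness is exactly linear in E", {
  g <- honeycomb_graph(2, 2, edge_len = 15, wall_thickness = 2)
  mesh <- graph_to_mesh(g, seed_size = 2)
  bcs <- apply_bcs(mesh, "right_stretch")
  K1 <- structural_stiffness(solve_frame(mesh, list(E = 1, nu = 0.3), bcs), bcs)
  K3 <- structural_stiffness(solve_frame(mesh, list(E = 3, nu = 0.3), bcs), bcs)
  expect_equal(K3 / K1, 3, tolerance = 1e-9)
  expect_gt(K1, 0)
})

test_that("thickness scaling exponent separates axial from bending regimes", {
  # straight bar: K proportional to t
  Kbar <- sapply(c(2, 6), function(t) {
    mesh <- graph_to_mesh(bar_graph(L = 10, t = t), seed_size = 1)
    bcs <- bar_axial_bcs(mesh)
    structural_stiffness(solve_frame(mesh, list(E = 1, nu = 0.3), bcs), bcs)
  })
  expect_equal(log(Kbar[2] / Kbar[1]) / log(3), 1, tolerance = 1e-9)

  # slender honeycomb: K ~ t^3 (fitted exponent in [2.8, 3.2])
  Khc <- sapply(c(2, 6), function(t) {
    g <- honeycomb_graph(3, 3, edge_len = 40, wall_thickness = t)
    mesh <- graph_to_mesh(g, seed_size = 2)
    bcs <- apply_bcs(mesh, "right_stretch")
    structural_stiffness(solve_frame(mesh, list(E = 1, nu = 0.3), bcs), bcs)
  })
  expo <- log(Khc[2] / Khc[1]) / log(3)
  expect_gt(expo, 2.8); expect_lt(expo, 3.2)
})

test_that("mesh refinement is converged at the 1 um seed", {
  g <- honeycomb_graph(2, 2, edge_len = 20, wall_thickness = 2)
  K <- sapply(c(1, 0.5), function(seed) {
    mesh <- graph_to_mesh(g, seed_size = seed)
    bcs <- apply_bcs(mesh, "right_stretch")
    structural_stiffness(solve_frame(mesh, list(E = 1, nu = 0.3), bcs), bcs)
  })
  expect_lt(abs(K[2] - K[1]) / K[1], 0.005)
})

test_that("apply_bcs presets select extreme bands and reject degenerate sets", {
  # unit square frame
  v <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  mk <- function(a, b) list(v = c(a, b),
                            points = as.matrix(rbind(v[a, ], v[b, ])),
                            thickness = 1)
  g <- new_wall_graph(v, list(mk(1, 2), mk(2, 3), mk(3, 4), mk(4, 1)),
                      unit = "um")
  mesh <- graph_to_mesh(g, seed_size = 1)
  bcs <- apply_bcs(mesh, "right_stretch", stretch = 1)
  right <- which(mesh$nodes[, 1] == 10)
  expect_setequal(bcs$prescribed$node, right)
  expect_true(all(bcs$prescribed$value == 1))
  expect_true(all(bcs$prescribed$dof == 1))

  bcs_top <- apply_bcs(mesh, "top_stretch", stretch = 1)
  top <- which(mesh$nodes[, 2] == 10)
  expect_setequal(bcs_top$prescribed$node, top)
  expect_true(all(bcs_top$prescribed$dof == 2))
  # two co-extreme top nodes are both driven
  expect_gt(length(bcs_top$prescribed$node), 1)

  expect_error(bc_spec(data.frame(node = 1, dof = 1),
                       data.frame(node = 1, dof = 1, value = 1)),
               "both fixed and prescribed")
})

test_that("element_von_mises recovers the textbook fiber stresses", {
  # pure axial: sigma = |N| / A
  mesh <- graph_to_mesh(bar_graph(L = 10, t = 2), seed_size = 10)
  bcs <- bar_axial_bcs(mesh, stretch = 0.1)
  res <- solve_frame(mesh, list(E = 1, nu = 0.3), bcs)
  vm <- element_von_mises(res)
  N <- 1 * 2 * 0.1 / 10
  expect_equal(vm, N / 2, tolerance = 1e-12)

  # combined N, V, M case against direct arithmetic
  L <- 8; t <- 1.2
  meshc <- graph_to_mesh(bar_graph(L = L, t = t), seed_size = L)
  left <- 1; tip <- 2
  bcsc <- bc_spec(fixed = data.frame(node = rep(left, 3), dof = 1:3),
                  prescribed = data.frame(node = tip, dof = c(1, 2),
                                          value = c(0.02, 0.05)))
  resc <- solve_frame(meshc, list(E = 2, nu = 0.25), bcsc)
  sec <- section_properties(t, 1)
  ef <- resc$end_forces
  byhand <- max(
    sqrt((abs(ef$N1) / sec$A + abs(ef$M1) * (t / 2) / sec$I)^2 +
           3 * (abs(ef$V1) / sec$As)^2),
    sqrt((abs(ef$N2) / sec$A + abs(ef$M2) * (t / 2) / sec$I)^2 +
           3 * (abs(ef$V2) / sec$As)^2))
  expect_equal(element_von_mises(resc), byhand, tolerance = 1e-12)
  expect_gt(abs(ef$M1), 0)  # the case genuinely bends
})

test_that("average_thickness reports the one-decimal mean", {
  expect_equal(average_thickness(c(3.7, 6.8, 2.0, 4.6)), 4.3)
  expect_equal(average_thickness(5), 5)
  expect_equal(average_thickness(c(2, 4)), 3)
  expect_error(average_thickness(numeric(0)), "empty")
})

test_that("INP export round-trips the model and is byte-stable", {
  g <- honeycomb_graph(2, 2, edge_len = 10, wall_thickness = 2)
  g$walls[[1]]$thickness <- 3.5          # two distinct sections
  mesh <- graph_to_mesh(g, seed_size = 2)
  bcs <- apply_bcs(mesh, "right_stretch")
  f1 <- tempfile(fileext = ".inp"); f2 <- tempfile(fileext = ".inp")
  export_inp(mesh, list(E = 1, nu = 0.3), bcs, f1)
  export_inp(mesh, list(E = 1, nu = 0.3), bcs, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_inp(f1)
  expect_equal(nrow(back$elements), nrow(mesh$elements))
  expect_equal(back$elements$n1, mesh$elements$n1)
  expect_equal(back$elements$n2, mesh$elements$n2)
  expect_equal(back$elements$thickness, mesh$elements$thickness)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-6)
  expect_equal(sum(grepl("BEAM SECTION", readLines(f1))), 2)

  # 1-element model: exactly 2 node lines and 1 element line
  m1 <- graph_to_mesh(bar_graph(L = 1, t = 1), seed_size = 1)
  f3 <- tempfile(fileext = ".inp")
  export_inp(m1, list(E = 1, nu = 0.3), NULL, f3)
  ln <- readLines(f3)
  node_at <- which(ln == "*NODE")
  elem_at <- grep("^\\*ELEMENT", ln)
  expect_equal(elem_at - node_at - 1, 2)
  next_kw <- which(startsWith(ln, "*") & seq_along(ln) > elem_at)[1]
  expect_equal(next_kw - elem_at - 1, 1)
})

test_that("overlay_stress colors extremes and preserves image size", {
  img <- raster_image(matrix(128, 40, 40), scale = 0.5)
  g <- new_wall_graph(data.frame(x = c(2, 17), y = c(10, 10)),
                      list(list(v = c(1L, 2L),
                                points = rbind(c(2, 10), c(17, 10)),
                                thickness = 2)), unit = "um")
  mesh <- graph_to_mesh(g, seed_size = 5)
  out <- overlay_stress(img, mesh, c(1, 2, 3), scale = 0.5)
  expect_equal(dim(out), c(40, 40, 3))
  out_u <- overlay_stress(img, mesh, c(2, 2, 2), scale = 0.5)
  drawn <- out_u[, , 3] == 255 & out_u[, , 1] == 0
  expect_gt(sum(drawn), 0)              # uniform stress renders all blue
})
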