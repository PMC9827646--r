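# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately avoid the package's compiled code paths.

# exact nearest-background distance by exhaustive search
oracle_edm <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(out)
  stopifnot(nrow(bg) > 0)
  for (k in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2
    out[fg[k, 1], fg[k, 2]] <- sqrt(min(d2))
  }
  out
}

# exhaustive nearest-particle-pixel Voronoi with smaller-label tie-breaking
oracle_voronoi <- function(lab) {
  src <- which(lab > 0, arr.ind = TRUE)
  stopifnot(nrow(src) > 0)
  src_lab <- lab[src]
  ord <- order(src_lab)          # ascending labels: first minimum wins ties
  src <- src[ord, , drop = FALSE]
  src_lab <- src_lab[ord]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_len(nrow(lab)))
    for (j in seq_len(ncol(lab))) {
      d2 <- (src[, 1] - i)^2 + (src[, 2] - j)^2
      out[i, j] <- src_lab[which.min(d2)]
    }
  out
}

# brute-force 3x3 median with edge replication
oracle_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      ii <- pmin(pmax(i + (-1:1), 1), nr)
      jj <- pmin(pmax(j + (-1:1), 1), nc)
      out[i, j] <- stats::median(m[ii, jj])
    }
  out
}

# brute-force 3x3 correlation with edge replication
oracle_conv3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1)
        acc <- acc + k[di + 2, dj + 2] *
          m[min(max(i + di, 1), nr), min(max(j + dj, 1), nc)]
      out[i, j] <- acc
    }
  out
}

random_mask <- function(seed, nr = NULL, nc = NULL, p = 0.5) {
  set.seed(seed)
  if (is.null(nr)) nr <- sample(3:32, 1)
  if (is.null(nc)) nc <- sample(3:32, 1)
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(!m)) m[1, 1] <- FALSE
  m
}

# a single straight horizontal wall of length L um and thickness t
bar_graph <- function(L = 10, t = 2) {
  new_wall_graph(data.frame(x = c(0, L), y = c(0, 0)),
                 list(list(v = c(1L, 2L),
                           points = rbind(c(0, 0), c(L, 0)),
                           thickness = t)),
                 unit = "um")
}

# axial tension BCs for a horizontal bar mesh: all left-end DOFs fixed,
# right end driven in x
bar_axial_bcs <- function(mesh, stretch = 0.1) {
  x <- mesh$nodes[, 1]
  left <- which(x == min(x)); right <- which(x == max(x))
  bc_spec(fixed = data.frame(node = rep(left, each = 3),
                             dof = rep(1:3, times = length(left))),
          prescribed = data.frame(node = right, dof = 1, value = stretch))
}
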