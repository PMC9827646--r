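#' Export a model as an Abaqus INP keyword file
#'
#' Writes the complete beam model in keyword format: `*NODE`, one
#' `*ELEMENT, TYPE=B21` block, an element set and a rectangular
#' `*BEAM SECTION` per distinct wall thickness, the elastic material, and a
#' single static step carrying the boundary and prescribed-displacement
#' lines (Abaqus DOF numbering: 1 = x, 2 = y, 6 = in-plane rotation).
#' Output is byte-stable for identical inputs.
#'
#' @param mesh an `fe_mesh`.
#' @param mat material, `list(E =, nu =)`.
#' @param bcs a `bc_spec`, or `NULL` to omit the step.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_inp <- function(mesh, mat = list(E = 1, nu = 0.3), bcs = NULL, path) {
  stopifnot(inherits(mesh, "fe_mesh"))
  ln <- c("*HEADING", "cell wall beam network model (units: um, force/um^2)")
  ln <- c(ln, "*NODE")
  ln <- c(ln, sprintf("%d, %.6f, %.6f", seq_len(nrow(mesh$nodes)),
                      mesh$nodes[, 1], mesh$nodes[, 2]))
  ln <- c(ln, "*ELEMENT, TYPE=B21, ELSET=WALLS")
  ln <- c(ln, sprintf("%d, %d, %d", seq_len(nrow(mesh$elements)),
                      mesh$elements$n1, mesh$elements$n2))
  th <- mesh$elements$thickness
  for (tv in sort(unique(th))) {
    set_name <- sprintf("T%s", gsub("[^0-9A-Za-z]", "_", format(tv)))
    ids <- which(th == tv)
    ln <- c(ln, sprintf("*ELSET, ELSET=%s", set_name))
    ln <- c(ln, vapply(split(ids, ceiling(seq_along(ids) / 16)),
                       function(chunk) paste(chunk, collapse = ", "),
                       character(1)))
    ln <- c(ln, sprintf("*BEAM SECTION, ELSET=%s, MATERIAL=WALL, SECTION=RECT",
                        set_name))
    ln <- c(ln, sprintf("%.6f, %.6f", tv, mesh$depth))
    ln <- c(ln, "0., 0., -1.")
  }
  ln <- c(ln, "*MATERIAL, NAME=WALL", "*ELASTIC",
          sprintf("%.9g, %.6f", mat$E, mat$nu))
  if (!is.null(bcs)) {
    dofmap <- c(1L, 2L, 6L)
    ln <- c(ln, "*STEP", "*STATIC", "*BOUNDARY")
    f <- bcs$fixed[order(bcs$fixed$node, bcs$fixed$dof), , drop = FALSE]
    ln <- c(ln, sprintf("%d, %d, %d", f$node, dofmap[f$dof], dofmap[f$dof]))
    p <- bcs$prescribed[order(bcs$prescribed$node), , drop = FALSE]
    ln <- c(ln, sprintf("%d, %d, %d, %.6f", p$node, dofmap[p$dof],
                        dofmap[p$dof], p$value))
    ln <- c(ln, "*END STEP")
  }
  writeLines(ln, path)
  invisible(path)
}

#' Minimal INP reader
#'
#' Parses files written by [export_inp()] (and similarly structured keyword
#' files): nodes, B21 elements, per-element thickness via the beam-section
#' element sets, elastic constants, and boundary lines.
#'
#' @param path INP file.
#' @return list with `nodes` (n x 2), `elements` (data frame `n1`, `n2`,
#'   `thickness`), `depth`, `mat`, `fixed`, `prescribed`.
#' @export
read_inp <- function(path) {
  ln <- readLines(path)
  is_kw <- startsWith(ln, "*")
  kw_of <- cumsum(is_kw)
  kws <- toupper(ln[is_kw])
  nodes <- NULL; el <- NULL; depth <- 1
  elsets <- list(); sec_thick <- c(); mat <- list(E = NA, nu = NA)
  fixed <- list(); pres <- list()
  dofmap_rev <- c(`1` = 1L, `2` = 2L, `6` = 3L)
  blocks <- split(seq_along(ln)[!is_kw], kw_of[!is_kw])
  for (bi in names(blocks)) {
    kw <- kws[as.integer(bi)]
    body <- ln[blocks[[bi]]]
    parts <- lapply(strsplit(body, ","), trimws)
    if (startsWith(kw, "*NODE")) {
      m <- do.call(rbind, lapply(parts, as.numeric))
      nodes <- m[order(m[, 1]), 2:3, drop = FALSE]
    } else if (startsWith(kw, "*ELEMENT")) {
      m <- do.call(rbind, lapply(parts, as.numeric))
      el <- data.frame(id = m[, 1], n1 = m[, 2], n2 = m[, 3])
    } else if (startsWith(kw, "*ELSET")) {
      name <- sub(".*ELSET=([^,]+).*", "\\1", kw)
      elsets[[name]] <- as.integer(unlist(parts))
    } else if (startsWith(kw, "*BEAM SECTION")) {
      name <- sub(".*ELSET=([^,]+).*", "\\1", kw)
      dims <- as.numeric(parts[[1]])
      sec_thick[name] <- dims[1]
      depth <- dims[2]
    } else if (startsWith(kw, "*ELASTIC")) {
      v <- as.numeric(parts[[1]])
      mat <- list(E = v[1], nu = v[2])
    } else if (startsWith(kw, "*BOUNDARY")) {
      for (p in parts) {
        v <- as.numeric(p)
        if (length(v) >= 4) {
          pres[[length(pres) + 1]] <-
            data.frame(node = v[1], dof = dofmap_rev[[as.character(v[2])]],
                       value = v[4])
        } else {
          fixed[[length(fixed) + 1]] <-
            data.frame(node = v[1], dof = dofmap_rev[[as.character(v[2])]])
        }
      }
    }
  }
  if (is.null(el)) stop("no elements found")
  el$thickness <- NA_real_
  for (name in names(sec_thick))
    el$thickness[match(elsets[[name]], el$id)] <- sec_thick[[name]]
  list(nodes = nodes,
       elements = el[order(el$id), c("n1", "n2", "thickness")],
       depth = depth, mat = mat,
       fixed = if (length(fixed)) do.call(rbind, fixed) else NULL,
       prescribed = if (length(pres)) do.call(rbind, pres) else NULL)
}
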