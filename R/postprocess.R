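# Derived fields (von Mises stress, equivalent strain), zone-wise
# summaries, and legacy-ASCII VTK export of meshes and solution states.

#' Von Mises equivalent stress
#'
#' `sqrt(3/2 dev(sigma):dev(sigma))` per Gauss point.
#'
#' @param state A `kfem_state` (or any object with a `sigma_gp` matrix of
#'   per-element Voigt Gauss-point stresses).
#' @return `E x 8` matrix (Pa).
#' @export
von_mises <- function(state) {
  sg <- state$sigma_gp
  E <- nrow(sg)
  out <- matrix(0, E, 8)
  for (q in 1:8) {
    v <- sg[, (q - 1) * 6 + (1:6), drop = FALSE]
    m <- (v[, 1] + v[, 2] + v[, 3]) / 3
    out[, q] <- sqrt(1.5 * ((v[, 1] - m)^2 + (v[, 2] - m)^2 +
                              (v[, 3] - m)^2 +
                              2 * (v[, 4]^2 + v[, 5]^2 + v[, 6]^2)))
  }
  out
}

#' Equivalent strain
#'
#' Scalar strain measure `(2/3) sqrt(3/2 dev(e):dev(e))` of the logarithmic
#' (Hencky) strain `e = (1/2) log(F F^T)` per Gauss point, normalized so a
#' uniaxial isochoric stretch `diag(exp(a), exp(-a/2), exp(-a/2))` reports
#' `a`.
#'
#' @param state A `kfem_state` (needs the `Fgp` matrix).
#' @return `E x 8` matrix (dimensionless).
#' @export
equivalent_strain <- function(state) {
  Fg <- state$Fgp
  E <- nrow(Fg)
  out <- matrix(0, E, 8)
  for (e in seq_len(E)) for (q in 1:8) {
    F <- matrix(Fg[e, (q - 1) * 9 + (1:9)], 3, 3)
    b <- F %*% t(F)
    ev <- eigen(b, symmetric = TRUE)
    le <- 0.5 * log(ev$values)
    d <- le - mean(le)
    out[e, q] <- (2 / 3) * sqrt(1.5 * sum(d^2))
  }
  out
}

# element means of a per-GP field
gp_element_mean <- function(gpfield) rowMeans(gpfield)

# volume-weighted nodal average of an element field (inverse-count average)
element_to_nodes <- function(mesh, efield) {
  N <- nrow(mesh$nodes)
  acc <- numeric(N); cnt <- numeric(N)
  for (a in 1:8) {
    ids <- mesh$elems[, a]
    acc[ids] <- acc[ids] + efield
    cnt[ids] <- cnt[ids] + 1
  }
  acc / pmax(cnt, 1)
}

#' Zone-wise field summary of a solved state
#'
#' Volume-weighted means and extrema of the von Mises stress and equivalent
#' strain per material zone, plus displacement extrema.
#'
#' @param mesh A `kfem_mesh`.
#' @param state A `kfem_state` on that mesh.
#' @return A data.frame, one row per zone present in the mesh.
#' @export
zone_summary <- function(mesh, state) {
  vm <- gp_element_mean(von_mises(state))
  eq <- gp_element_mean(equivalent_strain(state))
  vol <- element_volumes(mesh)
  umag <- sqrt(rowSums(state$u^2))
  emax_u <- vapply(seq_len(nrow(mesh$elems)), function(e)
    max(umag[mesh$elems[e, ]]), 0)
  zs <- sort(unique(mesh$zone))
  do.call(rbind, lapply(zs, function(z) {
    k <- mesh$zone == z
    data.frame(zone = z, n_elements = sum(k),
               volume_m3 = sum(vol[k]),
               von_mises_mean_pa = sum(vm[k] * vol[k]) / sum(vol[k]),
               von_mises_max_pa = max(vm[k]),
               eq_strain_mean = sum(eq[k] * vol[k]) / sum(vol[k]),
               eq_strain_max = max(eq[k]),
               max_disp_m = max(emax_u[k]))
  }))
}

#' Field report with extrema locations
#'
#' Locates the extrema of the derived fields: maximum nodal displacement
#' magnitude (node id), maximum element-mean von Mises stress and
#' equivalent strain (element ids with their zone, ring and through-
#' thickness layer; layer `n_layers` is the posterior-most).
#'
#' @param mesh A `kfem_mesh`.
#' @param state A `kfem_state`.
#' @return List: `max_disp` (`value_m`, `node`), `max_von_mises` /
#'   `max_eq_strain` (`value`, `element`, `zone`, `ring`, `layer`),
#'   `zone_summary` (the [zone_summary()] table).
#' @export
field_report <- function(mesh, state) {
  E <- nrow(mesh$elems)
  n_q <- E / mesh$n_layers
  el_layer <- (seq_len(E) - 1) %/% n_q + 1
  vm <- gp_element_mean(von_mises(state))
  eq <- gp_element_mean(equivalent_strain(state))
  umag <- sqrt(rowSums(state$u^2))
  loc <- function(v, e) list(value = v[e], element = e,
                             zone = mesh$zone[e], ring = mesh$ring[e],
                             layer = el_layer[e])
  list(max_disp = list(value_m = max(umag), node = which.max(umag)),
       max_von_mises = loc(vm, which.max(vm)),
       max_eq_strain = loc(eq, which.max(eq)),
       zone_summary = zone_summary(mesh, state))
}

#' Export a mesh and optional fields to legacy ASCII VTK
#'
#' Writes an unstructured-grid file (VTK DataFile 3.0, hexahedron cells)
#' with optional per-point vector data (`point_vectors`), per-point scalars
#' (`point_scalars`), and per-cell scalars (`cell_scalars`), each a named
#' list.  Numbers are written with full precision (`%.9e`), so files
#' round-trip through [read_vtk()] for testing.
#'
#' @param mesh A `kfem_mesh`.
#' @param path Output file path.
#' @param points Node coordinates to write (defaults to the reference
#'   nodes; pass `state$x` for the deformed grid).
#' @param point_vectors,point_scalars,cell_scalars Named lists of fields.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(mesh, path, points = mesh$nodes,
                       point_vectors = list(), point_scalars = list(),
                       cell_scalars = list()) {
  N <- nrow(points); E <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) sprintf("%.9e", x)
  w("# vtk DataFile Version 3.0")
  w("corneal finite-element model")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", N)
  writeLines(paste(num(points[, 1]), num(points[, 2]), num(points[, 3])),
             con)
  w("CELLS %d %d", E, 9 * E)
  writeLines(paste(8, mesh$elems[, 1] - 1, mesh$elems[, 2] - 1,
                   mesh$elems[, 3] - 1, mesh$elems[, 4] - 1,
                   mesh$elems[, 5] - 1, mesh$elems[, 6] - 1,
                   mesh$elems[, 7] - 1, mesh$elems[, 8] - 1), con)
  w("CELL_TYPES %d", E)
  writeLines(rep("12", E), con)
  if (length(point_vectors) || length(point_scalars)) {
    w("POINT_DATA %d", N)
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      w("VECTORS %s double", nm)
      writeLines(paste(num(v[, 1]), num(v[, 2]), num(v[, 3])), con)
    }
    for (nm in names(point_scalars)) {
      w("SCALARS %s double 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(num(point_scalars[[nm]]), con)
    }
  }
  if (length(cell_scalars)) {
    w("CELL_DATA %d", E)
    for (nm in names(cell_scalars)) {
      w("SCALARS %s double 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(num(cell_scalars[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid
#'
#' Minimal reader for the files written by [export_vtk()]: points,
#' hexahedron connectivity, and any `VECTORS` / `SCALARS` data arrays.
#'
#' @param path File path.
#' @return List: `points`, `cells` (1-based `E x 8`), `point_data`,
#'   `cell_data` (named lists).
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  find <- function(pat) grep(pat, ln)[1]
  ip <- find("^POINTS ")
  N <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- matrix(scan(text = ln[(ip + 1):(ip + N)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  ic <- find("^CELLS ")
  E <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cl <- matrix(scan(text = ln[(ic + 1):(ic + E)], quiet = TRUE),
               ncol = 9, byrow = TRUE)
  cells <- cl[, -1, drop = FALSE] + 1
  point_data <- list(); cell_data <- list()
  section <- ""
  i <- 1
  while (i <= length(ln)) {
    if (grepl("^POINT_DATA", ln[i])) section <- "point"
    if (grepl("^CELL_DATA", ln[i])) section <- "cell"
    if (grepl("^VECTORS ", ln[i])) {
      nm <- strsplit(ln[i], " ")[[1]][2]
      n <- if (section == "point") N else E
      v <- matrix(scan(text = ln[(i + 1):(i + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
      if (section == "point") point_data[[nm]] <- v else cell_data[[nm]] <- v
      i <- i + n
    } else if (grepl("^SCALARS ", ln[i])) {
      nm <- strsplit(ln[i], " ")[[1]][2]
      n <- if (section == "point") N else E
      v <- scan(text = ln[(i + 2):(i + 1 + n)], quiet = TRUE)
      if (section == "point") point_data[[nm]] <- v else cell_data[[nm]] <- v
      i <- i + n + 1
    }
    i <- i + 1
  }
  list(points = pts, cells = cells, point_data = point_data,
       cell_data = cell_data)
}

#' Export a solved state with standard fields
#'
#' Convenience wrapper around [export_vtk()] writing the deformed grid with
#' nodal displacements, nodal-averaged von Mises stress and equivalent
#' strain, and per-cell zone index.
#'
#' @param mesh A `kfem_mesh`.
#' @param state A `kfem_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_state_vtk <- function(mesh, state, path) {
  vm <- element_to_nodes(mesh, gp_element_mean(von_mises(state)))
  eq <- element_to_nodes(mesh, gp_element_mean(equivalent_strain(state)))
  export_vtk(mesh, path, points = state$x,
             point_vectors = list(displacement = state$u),
             point_scalars = list(von_mises = vm, eq_strain = eq),
             cell_scalars = list(zone = match(mesh$zone, kfem_zone_labels)))
}
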