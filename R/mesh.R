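# Structured, zone-conforming hexahedral meshing of the corneal solid.
#
# In-plane layout: a butterfly (O-grid) core covering the apex (an elliptic
# square-to-disc map, so no degenerate polar elements), `n_transition`
# annular layers out to the first ring boundary, then one annular band per
# circumferential zone so that every ring/sector boundary is a mesh line.
# The in-plane template is extruded through the thickness with `n_layers`
# element layers by transfinite interpolation between the anterior and
# posterior surfaces.

#' Mesh resolution specification
#'
#' @param n_layers Through-thickness element layers (default 4).
#' @param n_angular Angular element divisions per octant (must be even so
#'   that both the sector-boundary meridians and the axis meridians are mesh
#'   lines).
#' @param n_transition Radial divisions between the core and the first ring
#'   boundary.
#' @param ring_divisions Integer vector of radial divisions per annular band
#'   (one entry per band between consecutive ring boundaries, the last band
#'   being the limbus); defaults to 1 per band.
#' @return A `kfem_meshspec`.
#' @export
mesh_spec <- function(n_layers = 4, n_angular = 2, n_transition = 1,
                      ring_divisions = NULL) {
  stopifnot(n_layers >= 1, n_angular >= 1, n_angular %% 2 == 0,
            n_transition >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 n_angular = as.integer(n_angular),
                 n_transition = as.integer(n_transition),
                 ring_divisions = ring_divisions),
            class = "kfem_meshspec")
}

#' Closed-form element count of the structured mesh
#'
#' `L * (ns^2 + 4 ns nt + 8 a sum(r_i))` with `ns = 2 a` the core divisions
#' per side, `nt` the transition divisions and `r_i` the per-band radial
#' divisions.
#'
#' @param mspec A `kfem_meshspec`.
#' @param n_bands Number of annular bands (defaults to the length of
#'   `ring_divisions`).
#' @return Integer element count.
#' @export
count_elements <- function(mspec, n_bands = length(mspec$ring_divisions)) {
  a <- mspec$n_angular; ns <- 2L * a
  r <- mspec$ring_divisions
  if (is.null(r)) r <- rep(1L, n_bands)
  as.integer(mspec$n_layers *
               (ns^2 + 4L * ns * mspec$n_transition + 8L * a * sum(r)))
}

#' Generate the zone-conforming hexahedral mesh
#'
#' @param geom A `kfem_geometry`.
#' @param spec A `kfem_segmentation`; its ring radii become mesh circles.
#' @param mspec A `kfem_meshspec`.
#' @param rim_tilt_cap Maximum rim-face in-plane tilt as a fraction of the
#'   outermost band width; the rim cross-section is inclined toward the
#'   corneo-scleral interface angle but limited so coarse meshes stay valid.
#' @param rim_ray_center Optional length-3 point; when given, each rim node
#'   column is placed exactly on the straight line through this point and
#'   the column's mid-surface rim point (so the lateral cut surface is
#'   radial about the point).  Used with the radial-roller support in
#'   spherical-shell verification problems, where a radial cut makes the
#'   exact 1-D solution admissible; overrides the tilt heuristic.
#' @return A `kfem_mesh` with node coordinates (m), 8-node hex connectivity
#'   (VTK ordering), element zone/octant/ring tags, posterior pressure
#'   facets, limbus rim cross-sections and structured metadata.
#' @export
generate_mesh <- function(geom, spec = segmentation_spec(),
                          mspec = mesh_spec(), rim_tilt_cap = 0.35,
                          rim_ray_center = NULL) {
  a <- mspec$n_angular; ns <- 2L * a; nt <- mspec$n_transition
  L <- mspec$n_layers
  ring_radii <- spec$ring_radii
  rho_max <- geom$outer_radius
  if (abs(spec$outer_radius - rho_max) > 1e-12)
    spec$outer_radius <- rho_max
  n_bands <- length(ring_radii)        # last band: limbus_radius -> rho_max
  rdiv <- mspec$ring_divisions
  if (is.null(rdiv)) rdiv <- rep(1L, n_bands)
  stopifnot(length(rdiv) == n_bands, all(rdiv >= 1))

  n_st <- 8L * a                       # angular stations
  dth <- 2 * pi / n_st
  station_angles <- (0:(n_st - 1)) * dth

  ## ---- in-plane template ----------------------------------------------
  r1 <- ring_radii[1]
  r_core <- 0.5 * r1
  # radial circle stations: core boundary, transition to r1, then bands
  radii <- r_core
  radii <- c(radii, r_core + (seq_len(nt) / nt) * (r1 - r_core))
  band_bounds <- c(ring_radii, rho_max)
  for (b in seq_len(n_bands)) {
    lo <- band_bounds[b]; hi <- band_bounds[b + 1]
    radii <- c(radii, lo + (seq_len(rdiv[b]) / rdiv[b]) * (hi - lo))
  }
  n_circ <- length(radii)              # circle 1 = core boundary

  # core grid: parameter values chosen so the boundary nodes land exactly on
  # the uniform angular stations of the circles
  th_par <- seq(-pi / 4, pi / 4, length.out = ns + 1)
  pv <- sqrt(2) * sin(th_par)          # in [-1, 1]
  core_xy <- matrix(0, (ns + 1)^2, 2)
  core_idx <- function(i, j) i * (ns + 1L) + j + 1L   # i,j in 0..ns
  for (i in 0:ns) for (j in 0:ns) {
    u <- pv[i + 1]; v <- pv[j + 1]
    core_xy[core_idx(i, j), ] <- r_core *
      c(u * sqrt(1 - v^2 / 2), v * sqrt(1 - u^2 / 2))
  }
  n_core <- (ns + 1L)^2
  apex_ip <- core_idx(ns %/% 2L, ns %/% 2L)

  # in-plane nodes: core block then circles 2..n_circ
  n_ip <- n_core + (n_circ - 1L) * n_st
  ip_xy <- matrix(0, n_ip, 2)
  ip_xy[1:n_core, ] <- core_xy
  circ_ip <- matrix(NA_integer_, n_circ, n_st)   # ip index per (circle, station)
  for (c in 2:n_circ) for (s in 0:(n_st - 1)) {
    k <- n_core + (c - 2L) * n_st + s + 1L
    ip_xy[k, ] <- radii[c] * c(cos(station_angles[s + 1]),
                               sin(station_angles[s + 1]))
    circ_ip[c, s + 1] <- k
  }
  # core perimeter -> circle 1: snap each boundary node to its station
  bnd <- unique(c(core_idx(0, 0:ns), core_idx(ns, 0:ns),
                  core_idx(0:ns, 0), core_idx(0:ns, ns)))
  for (k in bnd) {
    ang <- atan2(ip_xy[k, 2], ip_xy[k, 1]) %% (2 * pi)
    s <- round(ang / dth) %% n_st
    if (abs(((ang - station_angles[s + 1] + pi) %% (2 * pi)) - pi) > 1e-8)
      stop("core boundary node does not align with an angular station")
    circ_ip[1, s + 1] <- k
  }
  if (anyNA(circ_ip[1, ]))
    stop("core perimeter does not cover all angular stations")

  ip_station <- rep(NA_integer_, n_ip)
  ip_circle <- rep(NA_integer_, n_ip)
  for (c in 1:n_circ) for (s in 1:n_st) {
    ip_station[circ_ip[c, s]] <- s - 1L
    ip_circle[circ_ip[c, s]] <- c
  }

  ## ---- in-plane quads (CCW in xy) --------------------------------------
  quads <- matrix(0L, 0, 4)
  qs <- vector("list", ns^2 + (n_circ - 1L) * n_st)
  q <- 0L
  for (i in 0:(ns - 1)) for (j in 0:(ns - 1)) {
    q <- q + 1L
    qs[[q]] <- c(core_idx(i, j), core_idx(i + 1, j),
                 core_idx(i + 1, j + 1), core_idx(i, j + 1))
  }
  for (c in 1:(n_circ - 1)) for (s in 0:(n_st - 1)) {
    sp <- (s + 1L) %% n_st
    q <- q + 1L
    qs[[q]] <- c(circ_ip[c, s + 1], circ_ip[c + 1, s + 1],
                 circ_ip[c + 1, sp + 1], circ_ip[c, sp + 1])
  }
  quads <- do.call(rbind, qs)
  n_q <- nrow(quads)

  ## ---- extrude through the thickness ------------------------------------
  rho_ip <- sqrt(rowSums(ip_xy^2))
  th_ip <- atan2(ip_xy[, 2], ip_xy[, 1])
  za <- geom$z_ant(rho_ip, th_ip)
  zp <- geom$z_post(rho_ip, th_ip)
  n_nodes <- (L + 1L) * n_ip
  nodes <- matrix(0, n_nodes, 3)
  # rim tilt: shift outermost-circle nodes toward the interface angle
  rim_ip <- circ_ip[n_circ, ]
  band_w <- rho_max - radii[n_circ - 1L]
  rim_ray <- NULL
  if (!is.null(rim_ray_center)) {
    # place each rim column on the straight line through rim_ray_center and
    # the column's mid-surface point; anchor it by intersecting the line
    # with the anterior and posterior surfaces (1-D root finds)
    C <- rim_ray_center
    rim_ray <- lapply(seq_len(n_st), function(s) {
      th <- station_angles[s]
      zm <- (geom$z_ant(rho_max, th) + geom$z_post(rho_max, th)) / 2
      Pm <- c(rho_max * cos(th), rho_max * sin(th), zm)
      d <- (Pm - C) / sqrt(sum((Pm - C)^2))
      hit <- function(zfun) {
        f <- function(t) {
          P <- C + t * d
          P[3] - zfun(sqrt(P[1]^2 + P[2]^2), atan2(P[2], P[1]))
        }
        t0 <- sqrt(sum((Pm - C)^2))
        span <- 0.75 * abs(geom$z_post(rho_max, th) -
                             geom$z_ant(rho_max, th)) + 1e-5
        C + stats::uniroot(f, c(t0 - span, t0 + span), tol = 1e-14)$root * d
      }
      list(ant = hit(geom$z_ant), post = hit(geom$z_post))
    })
  }
  for (l in 0:L) {
    f <- l / L
    idx <- l * n_ip + seq_len(n_ip)
    z <- za + f * (zp - za)
    xy <- ip_xy
    if (is.null(rim_ray)) {
      # outermost column inclined toward the corneo-scleral interface
      zm <- (za[rim_ip] + zp[rim_ip]) / 2
      dz <- (za[rim_ip] + f * (zp[rim_ip] - za[rim_ip])) - zm
      drho <- -dz * tan(geom$limbus_angle)
      drho <- pmin(pmax(drho, -rim_tilt_cap * band_w), rim_tilt_cap * band_w)
      scl <- (rho_max + drho) / rho_max
      xy[rim_ip, ] <- ip_xy[rim_ip, ] * scl
      rho_new <- rho_max + drho
      z[rim_ip] <- geom$z_ant(rho_new, th_ip[rim_ip]) +
        f * (geom$z_post(rho_new, th_ip[rim_ip]) -
               geom$z_ant(rho_new, th_ip[rim_ip]))
    } else {
      for (s in seq_len(n_st)) {
        P <- rim_ray[[s]]$ant + f * (rim_ray[[s]]$post - rim_ray[[s]]$ant)
        xy[rim_ip[s], ] <- P[1:2]
        z[rim_ip[s]] <- P[3]
      }
    }
    nodes[idx, 1:2] <- xy
    nodes[idx, 3] <- z
  }

  ## ---- hexahedra ---------------------------------------------------------
  elems <- matrix(0L, L * n_q, 8)
  e <- 0L
  for (l in 0:(L - 1)) for (k in seq_len(n_q)) {
    e <- e + 1L
    bot <- l * n_ip + quads[k, ]
    top <- (l + 1L) * n_ip + quads[k, ]
    elems[e, ] <- c(bot, top)
  }

  ## ---- element tags ------------------------------------------------------
  cent <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] + nodes[elems[, 3], ] +
             nodes[elems[, 4], ] + nodes[elems[, 5], ] + nodes[elems[, 6], ] +
             nodes[elems[, 7], ] + nodes[elems[, 8], ]) / 8
  cls <- classify_point(cent, spec)

  ## ---- posterior facets (outward normal toward +z, the pressure side) ----
  facets <- matrix(0L, n_q, 4)
  for (k in seq_len(n_q)) facets[k, ] <- L * n_ip + quads[k, ]

  ## ---- limbus rim cross-sections ----------------------------------------
  rim_sections <- lapply(1:n_st, function(s)
    vapply(0:L, function(l) as.integer(l * n_ip + circ_ip[n_circ, s]), 0L))

  mesh <- structure(list(
    nodes = nodes, elems = elems,
    zone = cls$zone, octant = cls$octant, ring = cls$ring,
    facets_post = facets, rim_sections = rim_sections,
    n_layers = L, n_ip = n_ip, apex_ip = apex_ip,
    inplane = list(xy = ip_xy, station = ip_station, circle = ip_circle,
                   rho = rho_ip, theta = th_ip),
    circle_radii = radii, station_angles = station_angles,
    circ_ip = circ_ip,
    ring_radii = ring_radii, outer_radius = rho_max,
    spec = spec, mspec = mspec),
    class = "kfem_mesh")

  jac <- element_min_jacobians(mesh)
  if (any(jac <= 0))
    stop("meshing failure: non-positive Jacobian in element ",
         which(jac <= 0)[1])
  mesh
}

#' @export
print.kfem_mesh <- function(x, ...) {
  cat("<kfem_mesh>", nrow(x$nodes), "nodes,", nrow(x$elems), "hexahedra,",
      x$n_layers, "layers\n")
  cat("  zones:", paste(names(table(x$zone)), table(x$zone),
                        collapse = ", "), "\n")
  invisible(x)
}

# Global node id of in-plane node `ip` on node layer `layer` (0..L).
node_id <- function(mesh, layer, ip) layer * mesh$n_ip + ip

#' Posterior pressure facets / limbus rim cross-sections
#'
#' Accessors for the boundary metadata built by [generate_mesh()]:
#' `posterior_facets` returns the 4-node quadrilateral facets of the
#' posterior surface (ordered so the outward normal points into the anterior
#' chamber, i.e. the pressure side); `rim_sections` returns one ordered
#' through-thickness node column per meridional station of the limbus rim.
#'
#' @param mesh A `kfem_mesh`.
#' @return A facet matrix, or a list of node-id vectors.
#' @export
posterior_facets <- function(mesh) mesh$facets_post

#' @rdname posterior_facets
#' @export
rim_sections <- function(mesh) mesh$rim_sections

# --- quadrature helpers (R side; assembly proper is compiled) -------------

# local corner coordinates, VTK hex ordering
hex_corners <- function() {
  cbind(xi  = c(-1, 1, 1, -1, -1, 1, 1, -1),
        eta = c(-1, -1, 1, 1, -1, -1, 1, 1),
        zet = c(-1, -1, -1, -1, 1, 1, 1, 1))
}

# trilinear shape gradients wrt local coords at (xi, eta, zet): 8 x 3
hex_dN <- function(xi, eta, zet) {
  cc <- hex_corners()
  cbind(cc[, 1] * (1 + eta * cc[, 2]) * (1 + zet * cc[, 3]),
        cc[, 2] * (1 + xi * cc[, 1]) * (1 + zet * cc[, 3]),
        cc[, 3] * (1 + xi * cc[, 1]) * (1 + eta * cc[, 2])) / 8
}

gauss2 <- 1 / sqrt(3)

# minimum Jacobian determinant over the 2x2x2 points, per element
element_min_jacobians <- function(mesh) {
  g <- gauss2
  pts <- expand.grid(xi = c(-g, g), eta = c(-g, g), zet = c(-g, g))
  jmin <- rep(Inf, nrow(mesh$elems))
  for (p in seq_len(nrow(pts))) {
    dN <- hex_dN(pts$xi[p], pts$eta[p], pts$zet[p])
    for (e in seq_len(nrow(mesh$elems))) {
      X <- mesh$nodes[mesh$elems[e, ], ]
      jmin[e] <- min(jmin[e], det(t(X) %*% dN))
    }
  }
  jmin
}

#' Element volumes by Gauss quadrature
#'
#' @param mesh A `kfem_mesh`.
#' @param nodes Optional replacement node coordinates.
#' @return Numeric vector of element volumes (m^3).
#' @export
element_volumes <- function(mesh, nodes = mesh$nodes) {
  g <- gauss2
  pts <- expand.grid(xi = c(-g, g), eta = c(-g, g), zet = c(-g, g))
  vol <- numeric(nrow(mesh$elems))
  for (p in seq_len(nrow(pts))) {
    dN <- hex_dN(pts$xi[p], pts$eta[p], pts$zet[p])
    for (e in seq_len(nrow(mesh$elems))) {
      X <- nodes[mesh$elems[e, ], ]
      vol[e] <- vol[e] + det(t(X) %*% dN)
    }
  }
  vol
}

# facet vector areas (sum of n * da over each bilinear quad, 2x2 Gauss)
facet_vector_areas <- function(nodes, facets) {
  g <- gauss2
  pts <- expand.grid(xi = c(-g, g), eta = c(-g, g))
  va <- matrix(0, nrow(facets), 3)
  for (p in seq_len(nrow(pts))) {
    xi <- pts$xi[p]; eta <- pts$eta[p]
    s <- c(-1, 1, 1, -1); t <- c(-1, -1, 1, 1)
    dNxi <- s * (1 + eta * t) / 4
    dNeta <- t * (1 + xi * s) / 4
    for (f in seq_len(nrow(facets))) {
      X <- nodes[facets[f, ], ]
      a1 <- drop(t(X) %*% dNxi); a2 <- drop(t(X) %*% dNeta)
      va[f, ] <- va[f, ] + c(a1[2] * a2[3] - a1[3] * a2[2],
                             a1[3] * a2[1] - a1[1] * a2[3],
                             a1[1] * a2[2] - a1[2] * a2[1])
    }
  }
  va
}
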