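# Multizone segmentation of the corneal solid: octant x circumferential
# material zones, zone-wise Holzapfel/Mooney-Rivlin parameters, collagen
# fiber frames, and the control-point set used by the inverse methods.

#' Zone labels of the multizone corneal model
#'
#' Four material zones: the strongly reinforced central / nasal-temporal /
#' superior-inferior zones, the transition zones, the weakly reinforced
#' central oblique zones, and the limbus (single circumferential fiber
#' family).
#'
#' @format Character vector of the four zone labels.
#' @export
kfem_zone_labels <- c("CENTRAL_NT_SI_STRONG", "TRANSITION",
                      "CENTRAL_OBLIQUE", "LIMBUS")

#' Segmentation specification
#'
#' Ring boundary diameters (default 2, 4, 6, 8, 10, 11 mm), octant sectors of
#' 45 degrees (+/- 22.5 degrees around the horizontal and vertical
#' meridians), and the zone-rule radii: the central disc (up to the 4 mm
#' diameter) is strongly reinforced in every octant, oblique octants are
#' weakly reinforced out to the 8 mm diameter and transitional from 8 to
#' 11 mm, and everything beyond the 11 mm diameter is limbus.
#'
#' @param ring_diameters_m Strictly increasing ring boundary diameters (m).
#' @param sector_half_width_deg Sector half-width around the horizontal and
#'   vertical meridians (deg); 22.5 tiles the circle with 8 octants.
#' @param outer_radius Limbus outer in-plane extent (m).
#' @param oblique_strong_radius Radius up to which oblique octants are
#'   labelled strong (m); default the 4 mm diameter.
#' @param transition_radius Radius beyond which oblique octants become
#'   transition zones (m); default the 8 mm diameter.
#' @return An object of class `kfem_segmentation`.
#' @export
segmentation_spec <- function(ring_diameters_m = c(2, 4, 6, 8, 10, 11) * 1e-3,
                              sector_half_width_deg = 22.5,
                              outer_radius = 6.0e-3,
                              oblique_strong_radius = 2e-3,
                              transition_radius = 4e-3) {
  stopifnot(all(diff(ring_diameters_m) > 0),
            sector_half_width_deg > 0,
            outer_radius > max(ring_diameters_m) / 2)
  structure(list(ring_diameters_m = ring_diameters_m,
                 ring_radii = ring_diameters_m / 2,
                 sector_half_width = sector_half_width_deg * pi / 180,
                 limbus_radius = max(ring_diameters_m) / 2,
                 outer_radius = outer_radius,
                 oblique_strong_radius = oblique_strong_radius,
                 transition_radius = transition_radius),
            class = "kfem_segmentation")
}

#' Classify a point into octant, ring, and material zone
#'
#' The octant is taken from `atan2(y, x)` with boundaries at the sector
#' half-width around the horizontal/vertical meridians (half-open
#' counterclockwise); the ring from the mid-thickness in-plane radius with
#' half-open intervals (a boundary radius belongs to the outer ring).  Zone
#' rule: beyond the 11 mm diameter the point is limbus; inside the 4 mm
#' diameter, and in the nasal-temporal / superior-inferior octants
#' everywhere, the strongly reinforced parameters apply; oblique octants are
#' weakly reinforced out to the 8 mm diameter and transitional beyond it.
#'
#' @param x Numeric length-3 position, or an `n x 3` matrix of positions (m);
#'   only the in-plane components enter the classification.
#' @param spec A `kfem_segmentation`.
#' @return A list (or data.frame for matrix input) with `octant` (1..8,
#'   octant 1 centered on +x), `ring` (1-based, outermost = limbus band) and
#'   `zone` (one of [kfem_zone_labels]).
#' @export
classify_point <- function(x, spec = segmentation_spec()) {
  if (is.matrix(x)) {
    res <- lapply(seq_len(nrow(x)), function(i) classify_point(x[i, ], spec))
    return(data.frame(octant = vapply(res, `[[`, 0L, "octant"),
                      ring = vapply(res, `[[`, 0L, "ring"),
                      zone = vapply(res, `[[`, "", "zone")))
  }
  rho <- sqrt(x[1]^2 + x[2]^2)
  if (rho > spec$outer_radius * (1 + 1e-9))
    stop("point lies outside the limbus outer extent")
  theta <- atan2(x[2], x[1]) %% (2 * pi)
  hw <- spec$sector_half_width
  # octant 1 spans [-hw, hw) around +x; half-open counterclockwise
  octant <- as.integer(floor((theta + hw) / (2 * hw)) %% 8) + 1L
  bounds <- c(0, spec$ring_radii, spec$outer_radius)
  ring <- findInterval(rho, bounds, left.open = FALSE, rightmost.closed = TRUE)
  ring <- max(1L, min(as.integer(ring), length(bounds) - 1L))
  axis_octant <- (octant %% 2L) == 1L
  zone <- if (rho >= spec$limbus_radius) "LIMBUS"
          else if (rho < spec$oblique_strong_radius || axis_octant)
            "CENTRAL_NT_SI_STRONG"
          else if (rho < spec$transition_radius) "CENTRAL_OBLIQUE"
          else "TRANSITION"
  list(octant = octant, ring = ring, zone = zone)
}

#' Zone-wise material parameters
#'
#' Returns the anisotropic hyperelastic parameter set of a zone: the
#' Mooney-Rivlin matrix constants `a1 = 40 kPa`, `a2 = -10 kPa` (identical in
#' all zones), the Holzapfel fiber constants `k1` (50 kPa strong/limbus,
#' 37.5 kPa transition, 25 kPa oblique) and `k2 = 200`, and the global bulk
#' factor `k0 = 5.5 MPa`.  The limbus carries a single (circumferential)
#' fiber family; all other zones carry two.
#'
#' @param label One of [kfem_zone_labels].
#' @param k0 Bulk factor (Pa).
#' @param overrides Optional named list of parameter overrides.
#' @return A list with `a1`, `a2`, `k1`, `k2`, `k0` (Pa except `k2`) and
#'   `n_families`.
#' @export
assign_parameters <- function(label, k0 = 5.5e6, overrides = NULL) {
  if (!label %in% kfem_zone_labels)
    stop("unknown zone label: ", label)
  k1 <- switch(label,
               CENTRAL_NT_SI_STRONG = 50000,
               TRANSITION = 37500,
               CENTRAL_OBLIQUE = 25000,
               LIMBUS = 50000)
  p <- list(a1 = 40000, a2 = -10000, k1 = k1, k2 = 200, k0 = k0,
            n_families = if (label == "LIMBUS") 1L else 2L)
  if (!is.null(overrides)) p[names(overrides)] <- overrides
  p
}

#' Fiber frame of an element
#'
#' In the corneal zones the two collagen families run along the
#' nasal-temporal (global x) and superior-inferior (global y) directions; in
#' the limbus a single family runs circumferentially, `(-sin t, cos t, 0)` at
#' azimuth `t`.  The second family of the limbus is returned for structural
#' completeness but flagged inactive (its energy contribution is dropped).
#'
#' @param centroid Length-3 element centroid (m).
#' @param label Zone label.
#' @return List with unit vectors `m0`, `n0` and logical `active2`.
#' @export
fiber_frame <- function(centroid, label) {
  if (label == "LIMBUS") {
    theta <- atan2(centroid[2], centroid[1])
    m0 <- c(-sin(theta), cos(theta), 0)
    n0 <- c(cos(theta), sin(theta), 0)  # radial placeholder, inactive
    list(m0 = m0, n0 = n0, active2 = FALSE)
  } else {
    list(m0 = c(1, 0, 0), n0 = c(0, 1, 0), active2 = TRUE)
  }
}

#' Control-point node set
#'
#' Returns the node ids monitored by the inverse iterative methods: the apex
#' node of the requested surface plus the surface nodes at each intersection
#' of a sector-boundary meridian with a ring boundary circle.  With the
#' default segmentation (8 sector-boundary meridians; circles at the 2, 4,
#' 6, 8, 10 and 11 mm diameters plus the limbus outer boundary) this yields
#' 8 x 7 + 1 = 57 control nodes per surface.
#'
#' @param mesh A `kfem_mesh` (zone-conforming; the meridians and circles must
#'   be mesh lines).
#' @param spec The `kfem_segmentation` used to mesh.
#' @param surface `"anterior"` or `"posterior"`.
#' @param meridian_angles Optional meridian angles (rad); default the sector
#'   boundaries.
#' @param circle_radii Optional circle radii (m); default the ring boundary
#'   radii plus the limbus outer boundary.
#' @return Integer vector of node ids, apex first, then ordered by circle
#'   then meridian.
#' @export
control_points <- function(mesh, spec = segmentation_spec(),
                           surface = c("anterior", "posterior"),
                           meridian_angles = NULL, circle_radii = NULL) {
  surface <- match.arg(surface)
  if (is.null(meridian_angles)) {
    hw <- spec$sector_half_width
    meridian_angles <- (hw + (0:7) * 2 * hw) %% (2 * pi)
  }
  if (is.null(circle_radii))
    circle_radii <- c(spec$ring_radii, mesh$outer_radius)
  layer <- if (surface == "anterior") 0L else mesh$n_layers

  station_of <- function(a) {
    d <- abs(((mesh$station_angles - a + pi) %% (2 * pi)) - pi)
    s <- which(d < 1e-7)
    if (!length(s))
      stop("mesh has no meridian line at angle ", a,
           " rad; mesh is not zone-conforming")
    s[1]
  }
  circle_of <- function(rr) {
    ci <- which(abs(mesh$circle_radii - rr) < 1e-9 + 1e-6 * rr)
    if (!length(ci))
      stop("mesh has no node circle at radius ", rr,
           " m; mesh is not zone-conforming")
    ci[1]
  }
  stations <- vapply(meridian_angles, station_of, 0L)
  circles <- vapply(circle_radii, circle_of, 0L)
  ids <- integer(0)
  for (ci in circles) for (s in stations)
    ids <- c(ids, node_id(mesh, layer, mesh$circ_ip[ci, s]))
  c(node_id(mesh, layer, mesh$apex_ip), ids)
}
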