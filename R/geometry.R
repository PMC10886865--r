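# Synthetic corneal geometries: biconic anterior/posterior surfaces with an
# optional decentered cone protrusion + thinning emulating keratoconus, and
# topographer-style polar elevation grids.
#
# Coordinate convention: apex at the origin, optical axis = +z pointing toward
# the interior of the eye (posterior side), x = nasal-temporal,
# y = superior-inferior.  All lengths in SI meters.

#' Biconic surface parameters
#'
#' Describes one corneal surface as a biconic: apical radii of curvature
#' `Rx`, `Ry` along the x (nasal-temporal) and y (superior-inferior)
#' meridians, asphericities `Qx`, `Qy`, and an apex offset along the optical
#' axis (used to place the posterior surface one central corneal thickness
#' behind the anterior one).
#'
#' @param Rx,Ry Apical radii of curvature (m), both `> 0`.
#' @param Qx,Qy Asphericities (dimensionless); `Q = 0` along both meridians
#'   with `Rx == Ry` gives a sphere.
#' @param role `"anterior"` or `"posterior"`.
#' @param apex_offset Apex position along +z (m); for the posterior surface
#'   this equals the central corneal thickness.
#' @return An object of class `kfem_biconic`.
#' @examples
#' biconic_params(7.8e-3, 7.8e-3)
#' @export
biconic_params <- function(Rx, Ry, Qx = 0, Qy = 0,
                           role = c("anterior", "posterior"),
                           apex_offset = 0) {
  role <- match.arg(role)
  stopifnot(is.numeric(Rx), is.numeric(Ry), Rx > 0, Ry > 0,
            is.finite(Qx), is.finite(Qy), apex_offset >= 0)
  structure(list(Rx = Rx, Ry = Ry, Qx = Qx, Qy = Qy,
                 role = role, apex_offset = apex_offset),
            class = "kfem_biconic")
}

# Sag of a biconic surface at cartesian (x, y), relative to its own apex.
biconic_sag <- function(p, x, y) {
  num <- x^2 / p$Rx + y^2 / p$Ry
  arg <- 1 - (1 + p$Qx) * x^2 / p$Rx^2 - (1 + p$Qy) * y^2 / p$Ry^2
  if (any(arg <= 0))
    stop("biconic surface undefined at the requested radius ",
         "(asphericity/radius combination leaves the conic domain)")
  num / (1 + sqrt(arg))
}

#' Cone protrusion/thinning perturbation (keratoconus surrogate)
#'
#' A Gaussian bump of elevation amplitude `amplitude` centered at polar
#' in-plane position (`r0`, `theta0`) with width `sigma`, protruding the
#' anterior surface outward (toward -z), combined with a local fractional
#' thickness reduction `thinning`.  This emulates the conical bulging and
#' stromal thinning of keratoconic corneas; it is a fixture convention, not a
#' clinical model.
#'
#' @param amplitude Elevation protrusion (m), `>= 0`.
#' @param r0,theta0 Polar position of the cone center (m, rad).
#' @param sigma Gaussian width (m), `> 0`.
#' @param thinning Fractional local thickness reduction in `[0, 1)`.
#' @return An object of class `kfem_cone`.
#' @export
cone_perturbation <- function(amplitude, r0 = 1.2e-3, theta0 = -pi / 3,
                              sigma = 1.5e-3, thinning = 0) {
  stopifnot(amplitude >= 0, sigma > 0, thinning >= 0, thinning < 1)
  structure(list(amplitude = amplitude, r0 = r0, theta0 = theta0,
                 sigma = sigma, thinning = thinning),
            class = "kfem_cone")
}

# Gaussian cone weight at in-plane (x, y).
cone_weight <- function(cone, x, y) {
  cx <- cone$r0 * cos(cone$theta0)
  cy <- cone$r0 * sin(cone$theta0)
  d2 <- (x - cx)^2 + (y - cy)^2
  exp(-d2 / (2 * cone$sigma^2))
}

#' Build a corneal solid geometry
#'
#' Combines an anterior and a posterior biconic surface (and optionally a
#' cone perturbation) into an evaluable corneal geometry.  Elevations are
#' measured along +z from the anterior apex; the posterior apex offset must
#' exceed the anterior one so that the central thickness is positive.  The
#' limbus band terminates at `outer_radius`, where the rim cross-section is
#' cut on a cone making `limbus_angle` with the coronal plane (the
#' corneo-scleral interface angle, default 40 degrees).
#'
#' @param anterior,posterior `kfem_biconic` surfaces.
#' @param cone Optional `kfem_cone` perturbation.
#' @param limbus_angle Corneo-scleral interface angle (rad), default
#'   `40 * pi / 180`.
#' @param outer_radius In-plane radius of the outer limbus boundary (m); must
#'   lie beyond the 11 mm diameter (5.5e-3 m).
#' @param check_n Resolution of the feasibility scan.
#' @return An object of class `kfem_geometry` with vectorized elevation
#'   functions `z_ant(r, theta)` and `z_post(r, theta)`.
#' @examples
#' geom <- default_cornea()
#' geom$z_ant(1e-3, 0)
#' @export
make_cornea <- function(anterior, posterior, cone = NULL,
                        limbus_angle = 40 * pi / 180,
                        outer_radius = 6.0e-3, check_n = 64) {
  stopifnot(inherits(anterior, "kfem_biconic"),
            inherits(posterior, "kfem_biconic"))
  cct <- posterior$apex_offset - anterior$apex_offset
  if (cct <= 0)
    stop("geometry infeasible: posterior apex offset must exceed the ",
         "anterior one by the central corneal thickness")
  if (outer_radius <= 5.5e-3)
    stop("outer_radius must lie beyond the 11 mm diameter (5.5e-3 m)")
  if (!is.null(cone)) stopifnot(inherits(cone, "kfem_cone"))

  z_ant <- function(r, theta) {
    x <- r * cos(theta); y <- r * sin(theta)
    z <- anterior$apex_offset + biconic_sag(anterior, x, y)
    if (!is.null(cone) && cone$amplitude > 0)
      z <- z - cone$amplitude * cone_weight(cone, x, y)
    z
  }
  z_post <- function(r, theta) {
    x <- r * cos(theta); y <- r * sin(theta)
    za <- anterior$apex_offset + biconic_sag(anterior, x, y)
    zp <- posterior$apex_offset + biconic_sag(posterior, x, y)
    t0 <- zp - za
    if (!is.null(cone)) {
      w <- cone_weight(cone, x, y)
      za <- za - cone$amplitude * w
      t0 <- t0 * (1 - cone$thinning * w)
    }
    za + t0
  }

  geom <- structure(list(z_ant = z_ant, z_post = z_post,
                         anterior = anterior, posterior = posterior,
                         cone = cone, limbus_angle = limbus_angle,
                         outer_radius = outer_radius,
                         central_thickness = cct,
                         source = "biconic"),
                    class = "kfem_geometry")

  # Feasibility: thickness positive everywhere on a scan grid.
  th <- thickness_grid(geom, n_r = check_n, n_theta = check_n)
  if (any(th$thickness <= 0))
    stop("geometry infeasible: cone thinning makes the posterior surface ",
         "cross the anterior surface")
  geom
}

#' @export
print.kfem_geometry <- function(x, ...) {
  cat("<kfem_geometry> (", x$source, ")\n", sep = "")
  cat("  central thickness:", format(x$central_thickness), "m\n")
  cat("  outer radius:     ", format(x$outer_radius), "m\n")
  cat("  limbus angle:     ", format(x$limbus_angle * 180 / pi), "deg\n")
  if (!is.null(x$cone))
    cat("  cone: A =", format(x$cone$amplitude), "m, thinning =",
        x$cone$thinning, "\n")
  invisible(x)
}

# Thickness (z_post - z_ant) sampled on a polar grid; used for feasibility
# and thickness-minimum checks.
thickness_grid <- function(geom, n_r = 64, n_theta = 64) {
  r <- seq(0, geom$outer_radius, length.out = n_r)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  g <- expand.grid(r = r, theta = theta)
  th <- geom$z_post(g$r, g$theta) - geom$z_ant(g$r, g$theta)
  list(r = g$r, theta = g$theta, thickness = th)
}

#' Default healthy cornea fixture
#'
#' Literature-standard average geometry: anterior radius 7.8 mm, posterior
#' radius 6.5 mm, central thickness 550 um, mild prolate asphericities
#' (anterior Q = -0.18, posterior Q = -0.38).  These are fixture values, not
#' claims about any particular eye.
#'
#' @param cone Optional `kfem_cone`; see [keratoconus_cone()].
#' @param outer_radius Limbus outer in-plane radius (m).
#' @return A `kfem_geometry`.
#' @export
default_cornea <- function(cone = NULL, outer_radius = 6.0e-3) {
  make_cornea(
    biconic_params(7.8e-3, 7.8e-3, Qx = -0.18, Qy = -0.18, role = "anterior"),
    biconic_params(6.5e-3, 6.5e-3, Qx = -0.38, Qy = -0.38,
                   role = "posterior", apex_offset = 5.5e-4),
    cone = cone, outer_radius = outer_radius)
}

#' Keratoconus severity fixtures
#'
#' Maps a severity grade `"G1"`..`"G4"` to a cone perturbation with
#' monotonically increasing protrusion amplitude and thinning fraction,
#' decentered inferotemporally.  The mapping is a fixture convention for
#' exercising the solver on progressively asymmetric geometries; it carries
#' no clinical claim of equivalence with graded patient corneas.
#'
#' @param grade One of `"G1"`, `"G2"`, `"G3"`, `"G4"`.
#' @return A `kfem_cone`.
#' @export
keratoconus_cone <- function(grade = c("G1", "G2", "G3", "G4")) {
  grade <- match.arg(grade)
  amp <- c(G1 = 5e-5, G2 = 9e-5, G3 = 1.4e-4, G4 = 2e-4)[[grade]]
  tf  <- c(G1 = 0.08, G2 = 0.18, G3 = 0.28, G4 = 0.40)[[grade]]
  cone_perturbation(amplitude = amp, r0 = 1.2e-3, theta0 = -pi / 3,
                    sigma = 1.5e-3, thinning = tf)
}

#' Sample a geometry onto a topographer-style polar grid
#'
#' Samples anterior and posterior elevations on a rectangular polar grid of
#' uniformly spaced meridians and radial stations, emulating the discrete
#' point set a Scheimpflug/Placido topographer delivers.
#'
#' @param geom A `kfem_geometry`.
#' @param n_meridians,n_radial Grid sizes, both `>= 8`.
#' @return A `kfem_topography` with fields `theta` (rad), `r` (m) and
#'   elevation matrices `z_ant`, `z_post` (meridian x radius).
#' @export
to_topography <- function(geom, n_meridians = 24, n_radial = 32) {
  stopifnot(n_meridians >= 8, n_radial >= 8)
  theta <- seq(0, 2 * pi, length.out = n_meridians + 1)[-(n_meridians + 1)]
  r <- seq(0, geom$outer_radius, length.out = n_radial)
  g <- expand.grid(theta = theta, r = r)   # meridian varies fastest
  za <- matrix(geom$z_ant(g$r, g$theta), nrow = n_meridians)
  zp <- matrix(geom$z_post(g$r, g$theta), nrow = n_meridians)
  structure(list(theta = theta, r = r, z_ant = za, z_post = zp),
            class = "kfem_topography")
}

#' @export
print.kfem_topography <- function(x, ...) {
  cat("<kfem_topography>", length(x$theta), "meridians x", length(x$r),
      "radial stations\n")
  invisible(x)
}

#' Write / read a topography grid as CSV
#'
#' Row-major meridian-then-radius ordering with header
#' `theta_rad,r_m,z_ant_m,z_post_m`; `NA` cells denote missing samples.
#'
#' @param grid A `kfem_topography`.
#' @param path File path.
#' @return `read_topography` returns a `kfem_topography`.
#' @export
write_topography <- function(grid, path) {
  g <- expand.grid(theta = grid$theta, r = grid$r)
  df <- data.frame(theta_rad = g$theta, r_m = g$r,
                   z_ant_m = as.vector(grid$z_ant),
                   z_post_m = as.vector(grid$z_post))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path) {
  df <- utils::read.csv(path)
  need <- c("theta_rad", "r_m", "z_ant_m", "z_post_m")
  if (!all(need %in% names(df)))
    stop("topography CSV must have columns ", paste(need, collapse = ", "))
  theta <- sort(unique(df$theta_rad))
  r <- sort(unique(df$r_m))
  if (nrow(df) != length(theta) * length(r))
    stop("topography grid is not rectangular")
  idx <- order(df$r_m, df$theta_rad)
  df <- df[idx, ]
  za <- matrix(df$z_ant_m, nrow = length(theta))
  zp <- matrix(df$z_post_m, nrow = length(theta))
  structure(list(theta = theta, r = r, z_ant = za, z_post = zp),
            class = "kfem_topography")
}

# Fill missing cells of one elevation matrix by periodic linear interpolation
# across meridians (angular neighbors) at fixed radius; falls back to radial
# interpolation when a full angular ring is missing.
fill_missing_polar <- function(z, theta, r) {
  n_m <- nrow(z)
  for (j in seq_len(ncol(z))) {
    col <- z[, j]
    if (anyNA(col)) {
      if (all(is.na(col))) next
      ok <- which(!is.na(col))
      # periodic extension for interpolation across the wrap
      xs <- c(theta[ok] - 2 * pi, theta[ok], theta[ok] + 2 * pi)
      ys <- rep(col[ok], 3)
      z[, j] <- stats::approx(xs, ys, xout = theta)$y
    }
  }
  # any ring still fully missing: interpolate radially per meridian
  for (i in seq_len(n_m)) {
    row <- z[i, ]
    if (anyNA(row)) {
      ok <- which(!is.na(row))
      z[i, ] <- stats::approx(r[ok], row[ok], xout = r, rule = 2)$y
    }
  }
  z
}

#' Reconstruct a smooth corneal geometry from a topography grid
#'
#' Fits each surface with a radial cubic spline per meridian followed by a
#' periodic cubic interpolation across meridians (a smooth polar
#' interpolant); missing cells are first filled by interpolation between
#' angular neighbors.  The returned surfaces interpolate the grid at its
#' knots.
#'
#' @param grid A `kfem_topography` (rectangular; `NA` cells allowed).
#' @param limbus_angle,outer_radius See [make_cornea()].
#' @return A `kfem_geometry`.
#' @export
from_topography <- function(grid, limbus_angle = 40 * pi / 180,
                            outer_radius = NULL) {
  stopifnot(inherits(grid, "kfem_topography"))
  if (is.null(dim(grid$z_ant)) ||
      !all(dim(grid$z_ant) == c(length(grid$theta), length(grid$r))) ||
      !all(dim(grid$z_post) == dim(grid$z_ant)))
    stop("topography grid is not rectangular")
  if (is.null(outer_radius)) outer_radius <- max(grid$r)
  theta <- grid$theta
  za <- fill_missing_polar(grid$z_ant, theta, grid$r)
  zp <- fill_missing_polar(grid$z_post, theta, grid$r)

  make_eval <- function(zmat) {
    # one radial spline per meridian, built once
    sfuns <- lapply(seq_along(theta), function(i)
      stats::splinefun(grid$r, zmat[i, ], method = "natural"))
    thetas_ext <- c(theta, theta[1] + 2 * pi)
    function(r, th) {
      n <- max(length(r), length(th))
      r <- rep_len(r, n); th <- rep_len(th, n) %% (2 * pi)
      vals <- vapply(sfuns, function(f) f(r), numeric(n))
      vals <- matrix(vals, nrow = n)          # n x n_meridians
      out <- numeric(n)
      for (k in seq_len(n)) {
        yext <- c(vals[k, ], vals[k, 1])
        out[k] <- stats::spline(thetas_ext, yext, method = "periodic",
                                xout = th[k])$y
      }
      out
    }
  }

  z_ant <- make_eval(za)
  z_post <- make_eval(zp)
  cct <- z_post(0, 0) - z_ant(0, 0)
  structure(list(z_ant = z_ant, z_post = z_post,
                 anterior = NULL, posterior = NULL, cone = NULL,
                 limbus_angle = limbus_angle, outer_radius = outer_radius,
                 central_thickness = cct, source = "topography"),
            class = "kfem_geometry")
}

#' Maximum anterior tangential (meridional) curvature
#'
#' Scans meridians on a fine polar grid and returns the maximum meridional
#' curvature of the anterior surface, `|z''| / (1 + z'^2)^(3/2)`, evaluated
#' by central finite differences.  Used as the severity measure of cone
#' fixtures: steeper cones have larger maximum tangential curvature.
#'
#' @param geom A `kfem_geometry`.
#' @param n_theta,n_r Scan resolution.
#' @param r_max Scan extent (m); defaults to the 8 mm diameter zone.
#' @return Maximum curvature (1/m).
#' @export
anterior_curvature_max <- function(geom, n_theta = 48, n_r = 101,
                                   r_max = 4e-3) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  # signed radial coordinate so the meridian passes through the apex
  s <- seq(-r_max, r_max, length.out = n_r)
  h <- s[2] - s[1]
  kmax <- 0
  for (th in theta) {
    z <- geom$z_ant(abs(s), ifelse(s >= 0, th, th + pi))
    zp <- (z[3:n_r] - z[1:(n_r - 2)]) / (2 * h)
    zpp <- (z[3:n_r] - 2 * z[2:(n_r - 1)] + z[1:(n_r - 2)]) / h^2
    kmax <- max(kmax, abs(zpp) / (1 + zp^2)^1.5)
  }
  kmax
}
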