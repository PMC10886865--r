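# Independent semi-analytic reference solution: pressurized thick-walled
# spherical shell of the isotropic (fiber-free) compressible Mooney-Rivlin
# material, solved as a 1-D two-point boundary value problem in the radial
# coordinate by shooting.  Serves as a verification oracle for the 3-D
# finite-element solver on a spherical-cap mesh with radial-roller support.

# Cauchy stress components of the spherically symmetric state
# F = diag(lr, lt, lt): returns c(sigma_rr, sigma_theta)
sphere_sigma <- function(lr, lt, params) {
  J <- lr * lt^2
  Jm23 <- J^(-2 / 3)
  br <- Jm23 * lr^2
  bt <- Jm23 * lt^2
  I1 <- br + 2 * bt
  sr <- (params$a1 + I1 * params$a2) * br - params$a2 * br^2
  st <- (params$a1 + I1 * params$a2) * bt - params$a2 * bt^2
  trS <- sr + 2 * st
  c(params$k0 * (J - 1) + (2 / J) * (sr - trS / 3),
    params$k0 * (J - 1) + (2 / J) * (st - trS / 3))
}

# invert sigma_rr(lr; lt) = target for the radial stretch
sphere_lr <- function(lt, target, params) {
  f <- function(lr) sphere_sigma(lr, lt, params)[1] - target
  stats::uniroot(f, c(0.2, 5), tol = 1e-13)$root
}

#' Reference solution: inflated thick spherical shell
#'
#' Solves the radial equilibrium of a compressible isotropic Mooney-Rivlin
#' spherical shell (`sigma_rr' = 2 (sigma_tt - sigma_rr) / r` in the current
#' configuration) under internal pressure `p_pa` and a traction-free outer
#' surface, by shooting on the inner current radius with [deSolve::ode()].
#' The material is the fiber-free reduction of the corneal model (same
#' `a1`, `a2`, `k0`).
#'
#' @param Ri,Ro Inner / outer reference radii (m).
#' @param p_pa Internal pressure (Pa).
#' @param params Parameter list with `a1`, `a2`, `k0` (fiber constants are
#'   ignored); default the strong-zone set.
#' @param n_grid Radial output stations.
#' @return List: `R` (reference radii), `r` (current radii), `u = r - R`,
#'   `sigma_rr`, `sigma_tt`, `u_inner`, `u_outer`, and the residual outer
#'   traction `srr_outer` of the converged shot.
#' @export
sphere_inflation_reference <- function(Ri, Ro, p_pa,
                                       params = assign_parameters(
                                         "CENTRAL_NT_SI_STRONG"),
                                       n_grid = 101) {
  stopifnot(Ro > Ri, Ri > 0, p_pa >= 0)
  Rs <- seq(Ri, Ro, length.out = n_grid)
  rhs <- function(R, y, parms) {
    r <- y[1]; srr <- y[2]
    lt <- r / R
    lr <- sphere_lr(lt, srr, params)
    sg <- sphere_sigma(lr, lt, params)
    list(c(lr, lr * 2 * (sg[2] - sg[1]) / r))
  }
  shoot <- function(ri) {
    sol <- deSolve::ode(c(r = ri, srr = -p_pa), Rs, rhs, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    sol[nrow(sol), "srr"]
  }
  # inflation moves the inner surface outward; bracket around Ri
  ri <- stats::uniroot(shoot, c(Ri * 0.999, Ri * 1.2), tol = 1e-14)$root
  sol <- deSolve::ode(c(r = ri, srr = -p_pa), Rs, rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  r <- sol[, "r"]; srr <- sol[, "srr"]
  stt <- vapply(seq_along(Rs), function(k) {
    lt <- r[k] / Rs[k]
    sphere_sigma(sphere_lr(lt, srr[k], params), lt, params)[2]
  }, 0)
  list(R = Rs, r = unname(r), u = unname(r - Rs),
       sigma_rr = unname(srr), sigma_tt = stt,
       u_inner = unname(r[1] - Ri), u_outer = unname(r[n_grid] - Ro),
       srr_outer = unname(srr[n_grid]))
}

#' Spherical-cap verification fixture
#'
#' A uniform-thickness spherical-cap geometry (concentric spherical anterior
#' and posterior surfaces) whose exact inflation response is the 1-D shell
#' solution of [sphere_inflation_reference()] when meshed, made isotropic
#' (`k1 = 0` in every zone), supported by the radial-roller condition about
#' the sphere center, and pressurized on the posterior (inner) surface.
#'
#' @param R_outer Anterior (outer) sphere radius (m).
#' @param thickness Shell thickness (m).
#' @param outer_radius In-plane cap extent (m).
#' @return List: `geometry` (a `kfem_geometry`), `center` (sphere center,
#'   for [build_bc()] and the mesher's `rim_ray_center`), `Ri`, `Ro`, and
#'   `mesh` (the verification-default `kfem_meshspec`; pass
#'   `rim_ray_center = center` to [generate_mesh()] so the lateral cut is
#'   radial and the 1-D solution is admissible under the roller support).
#' @export
spherical_cap_fixture <- function(R_outer = 7.8e-3, thickness = 5.5e-4,
                                  outer_radius = 6e-3) {
  geom <- make_cornea(
    biconic_params(R_outer, R_outer, 0, 0, role = "anterior"),
    biconic_params(R_outer - thickness, R_outer - thickness, 0, 0,
                   role = "posterior", apex_offset = thickness),
    outer_radius = outer_radius)
  list(geometry = geom, center = c(0, 0, R_outer),
       Ri = R_outer - thickness, Ro = R_outer,
       mesh = mesh_spec(n_angular = 4, n_transition = 2,
                        ring_divisions = rep(2L, 6)))
}
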