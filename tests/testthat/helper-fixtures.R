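# Shared small fixtures, built lazily and cached for the session.

.kfem_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.kfem_test_cache[[key]]))
    assign(key, force(expr), envir = .kfem_test_cache)
  .kfem_test_cache[[key]]
}

# coarsest full-physics mesh (512 elements)
tiny_mesh <- function() cached("tiny_mesh",
  generate_mesh(default_cornea(), segmentation_spec(), mesh_spec()))

# even lighter mesh for inverse/CLI exercises (256 elements, 2 layers)
mini_spec <- function() mesh_spec(n_layers = 2)

mini_mesh <- function(cone = NULL) {
  key <- paste0("mini_mesh_", if (is.null(cone)) "none" else cone$amplitude)
  cached(key, generate_mesh(default_cornea(cone = cone),
                            segmentation_spec(), mini_spec()))
}

# isotropic override (kills the fiber families in every zone)
iso_overrides <- function()
  stats::setNames(rep(list(list(k1 = 0)), length(kfem_zone_labels)),
                  kfem_zone_labels)

random_small_F <- function(sd = 0.03) diag(3) + matrix(rnorm(9, sd = sd), 3, 3)

# independent finite-difference Cauchy stress from the strain energy,
# differentiating through C (sqrt-of-C path, independent of cauchy_stress)
fd_cauchy <- function(F, params, frame, h = 1e-7, tension_only = FALSE) {
  psi_of_C <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    Fc <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
    strain_energy(kinematics(Fc), params, frame, tension_only)
  }
  C <- t(F) %*% F
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dC <- matrix(0, 3, 3); dC[i, j] <- dC[j, i] <- h
    d <- (psi_of_C(C + dC) - psi_of_C(C - dC)) / (2 * h)
    # S = 2 dpsi/dC; the symmetric perturbation already doubles the
    # off-diagonal sensitivities, the diagonal needs the explicit factor
    S[i, j] <- S[j, i] <- if (i == j) 2 * d else d
  }
  F %*% S %*% t(F) / det(F)
}

# spherical-shell verification problem: solve the cap model with radial
# rollers and isotropic parameters, returning apex radial displacements of
# the outer (anterior) and inner (posterior) surfaces
sphere_solve_cap <- function(fix, ms) {
  mesh <- generate_mesh(fix$geometry, segmentation_spec(), ms,
                        rim_ray_center = fix$center)
  mats <- material_assignment(mesh, overrides = iso_overrides())
  bc <- build_bc(mesh, "radial_roller", center = fix$center)
  st <- solve_forward(mesh, mats, bc, 15)
  c(outer = -st$u[mesh$apex_ip, 3],
    inner = -st$u[mesh$n_layers * mesh$n_ip + mesh$apex_ip, 3])
}

# a one-hex "mesh-like" element set on a distorted unit-ish cube (meters)
single_hex <- function(distort = 0) {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)) * 1e-3
  if (distort > 0) {
    set.seed(42)
    X <- X + matrix(rnorm(24, sd = distort * 1e-3), 8, 3)
  }
  list(nodes = X, elems = matrix(1:8, 1, 8))
}

hex_materials <- function(label = "CENTRAL_NT_SI_STRONG", k1 = NULL) {
  p <- assign_parameters(label)
  if (!is.null(k1)) p$k1 <- k1
  list(mat_par = matrix(c(p$a1, p$a2, p$k1, p$k2, p$k0), 1, 5),
       fibers = matrix(c(1, 0, 0, 0, 1, 0), 1, 6),
       active2 = 1L)
}
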