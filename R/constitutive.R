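# Quasi-incompressible anisotropic hyperelastic model of corneal stroma:
# a two-parameter Mooney-Rivlin matrix plus up to two exponential
# (Holzapfel-type) collagen fiber families, with an isochoric/volumetric
# split and a quadratic volumetric penalty
#
#   psi = k0/2 (J-1)^2 + a1 (I1b - 3) + a2 (I2b - 3)
#         + sum_families k1/(2 k2) (exp[k2 (I4b - 1)^2] - 1)
#
# where the barred invariants are built from the modified right Cauchy-Green
# tensor Cb = J^(-2/3) C.  By default the fiber term is active in both
# extension and compression (the symmetric form); a conventional
# tension-only switch is available.

#' Kinematic quantities from a deformation gradient
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return A `kfem_kinematics` list: `F`, `J`, `Fbar = J^(-1/3) F`,
#'   `C`, `Cbar`, `bbar`.
#' @export
kinematics <- function(F) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("non-positive det(F): deformation state is inadmissible")
  Fbar <- J^(-1 / 3) * F
  structure(list(F = F, J = J, Fbar = Fbar,
                 C = t(F) %*% F, Cbar = t(Fbar) %*% Fbar,
                 bbar = Fbar %*% t(Fbar)),
            class = "kfem_kinematics")
}

#' Modified (isochoric) invariants
#'
#' Computes the nine barred invariants of the modified right Cauchy-Green
#' tensor and the two fiber structural tensors: `I1b = tr(Cb)`,
#' `I2b = ((tr Cb)^2 - tr(Cb^2))/2`, the squared fiber stretches
#' `I4b = m0.Cb.m0` and `I6b = n0.Cb.n0`, the transverse measures
#' `I5b = m0.Cb^2.m0`, `I7b = n0.Cb^2.n0`, the coupling `I8b = m0.Cb.n0`,
#' and the deformation-independent `I9 = (m0.n0)^2`.  Only `I1b`, `I2b`,
#' `I4b` and `I6b` enter the strain energy; the rest are reported for
#' completeness.
#'
#' @param kin A `kfem_kinematics`.
#' @param frame A fiber frame (see [fiber_frame()]).
#' @return Named list `I1`..`I9` (barred values).
#' @export
invariants <- function(kin, frame) {
  Cb <- kin$Cbar
  m0 <- frame$m0; n0 <- frame$n0
  Cb2 <- Cb %*% Cb
  tr <- function(A) sum(diag(A))
  list(I1 = tr(Cb),
       I2 = 0.5 * (tr(Cb)^2 - tr(Cb2)),
       I3 = det(Cb),
       I4 = drop(m0 %*% Cb %*% m0),
       I5 = drop(m0 %*% Cb2 %*% m0),
       I6 = drop(n0 %*% Cb %*% n0),
       I7 = drop(n0 %*% Cb2 %*% n0),
       I8 = drop(m0 %*% Cb %*% n0),
       I9 = drop(crossprod(m0, n0))^2)
}

# first/second energy derivatives wrt the fiber invariant; guards overflow
fiber_dpsi <- function(I4, k1, k2, tension_only = FALSE) {
  w <- I4 - 1
  if (tension_only && w <= 0) return(c(0, 0))
  ex <- k2 * w^2
  if (ex > 500)
    stop("fiber overextension: exp(k2 (I4-1)^2) overflows at I4 = ", I4)
  e <- exp(ex)
  c(d1 = k1 * w * e, d2 = k1 * e * (1 + 2 * k2 * w^2))
}

#' Strain energy density
#'
#' @param kin A `kfem_kinematics`.
#' @param params Material parameters (see [assign_parameters()]).
#' @param frame Fiber frame; its `active2` flag drops the second family
#'   (limbus).
#' @param tension_only If `TRUE`, fiber terms act only for `I4b > 1`.
#' @return Energy density (Pa).
#' @export
strain_energy <- function(kin, params, frame, tension_only = FALSE) {
  iv <- invariants(kin, frame)
  fib <- function(I4) {
    w <- I4 - 1
    if (tension_only && w <= 0) return(0)
    ex <- params$k2 * w^2
    if (ex > 500)
      stop("fiber overextension: exp(k2 (I4-1)^2) overflows at I4 = ", I4)
    params$k1 / (2 * params$k2) * (exp(ex) - 1)
  }
  psi <- 0.5 * params$k0 * (kin$J - 1)^2 +
    params$a1 * (iv$I1 - 3) + params$a2 * (iv$I2 - 3) + fib(iv$I4)
  if (isTRUE(frame$active2)) psi <- psi + fib(iv$I6)
  psi
}

#' Cauchy stress
#'
#' Total Cauchy stress of the decoupled model: the volumetric branch
#' `sigma_vol = k0 (J - 1) 1 = -p 1`, plus the isochoric branch
#' `(2/J) dev[ (psi1 + I1b psi2) bb - psi2 bb^2 + psi4 m x m + psi6 n x n ]`
#' with `psi1 = a1`, `psi2 = a2`,
#' `psi4 = k1 (I4b - 1) exp(k2 (I4b - 1)^2)` (same form for `psi6`), and
#' `m = Fbar m0`, `n = Fbar n0` the deformed fiber directions.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress (Pa).
#' @export
cauchy_stress <- function(kin, params, frame, tension_only = FALSE) {
  iv <- invariants(kin, frame)
  bb <- kin$bbar
  m <- drop(kin$Fbar %*% frame$m0)
  n <- drop(kin$Fbar %*% frame$n0)
  psi4 <- fiber_dpsi(iv$I4, params$k1, params$k2, tension_only)[1]
  psi6 <- if (isTRUE(frame$active2))
    fiber_dpsi(iv$I6, params$k1, params$k2, tension_only)[1] else 0
  S <- (params$a1 + iv$I1 * params$a2) * bb - params$a2 * (bb %*% bb) +
    psi4 * tcrossprod(m) + psi6 * tcrossprod(n)
  dev <- S - sum(diag(S)) / 3 * diag(3)
  params$k0 * (kin$J - 1) * diag(3) + (2 / kin$J) * dev
}

# --- Voigt helpers (order 11, 22, 33, 12, 23, 13) -------------------------

voigt_idx <- cbind(i = c(1, 2, 3, 1, 2, 1), j = c(1, 2, 3, 2, 3, 3))

to_voigt <- function(A) A[voigt_idx]

from_voigt <- function(v) {
  A <- matrix(0, 3, 3)
  A[voigt_idx] <- v
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# Voigt matrix of the symmetrized product (A (x) A)_ijkl =
# (A_ik A_jl + A_il A_jk)/2 for symmetric A
voigt_sym_outer <- function(A) {
  D <- matrix(0, 6, 6)
  for (I in 1:6) for (Jv in 1:6) {
    i <- voigt_idx[I, 1]; j <- voigt_idx[I, 2]
    k <- voigt_idx[Jv, 1]; l <- voigt_idx[Jv, 2]
    D[I, Jv] <- 0.5 * (A[i, k] * A[j, l] + A[i, l] * A[j, k])
  }
  D
}

voigt_one <- c(1, 1, 1, 0, 0, 0)
voigt_Is <- diag(c(1, 1, 1, 0.5, 0.5, 0.5))
voigt_W <- diag(c(1, 1, 1, 2, 2, 2))   # contraction weights

#' Spatial material tangent (Voigt 6x6)
#'
#' Consistent spatial elasticity modulus of the model, returned as the 6x6
#' Voigt matrix of `c/J`, where `c` is the Kirchhoff-stress modulus of the
#' decoupled energy (volumetric penalty + deviatoric projection of the
#' fictitious Mooney-Rivlin/fiber modulus).  It pairs with the
#' initial-stress (geometric) term in an updated-Lagrangian assembly, and
#' matches directional finite differences of [cauchy_stress()] through the
#' standard push-forward relation.
#'
#' @inheritParams strain_energy
#' @return 6x6 matrix (Pa), minor-symmetric by construction.
#' @export
material_tangent <- function(kin, params, frame, tension_only = FALSE) {
  iv <- invariants(kin, frame)
  J <- kin$J
  bb <- kin$bbar
  m <- drop(kin$Fbar %*% frame$m0)
  n <- drop(kin$Fbar %*% frame$n0)
  f4 <- fiber_dpsi(iv$I4, params$k1, params$k2, tension_only)
  f6 <- if (isTRUE(frame$active2))
    fiber_dpsi(iv$I6, params$k1, params$k2, tension_only) else c(0, 0)

  # fictitious Kirchhoff stress and its deviator
  tau_t <- 2 * ((params$a1 + iv$I1 * params$a2) * bb -
                  params$a2 * (bb %*% bb) +
                  f4[1] * tcrossprod(m) + f6[1] * tcrossprod(n))
  tr_tau <- sum(diag(tau_t))
  tau_iso <- tau_t - tr_tau / 3 * diag(3)

  # fictitious modulus (second derivatives wrt invariants)
  A2 <- iv$I1 * bb - bb %*% bb            # push-forward of dI2b/dCb
  vb <- to_voigt(bb)
  v2 <- to_voigt(A2)
  v4 <- to_voigt(tcrossprod(m))
  v6 <- to_voigt(tcrossprod(n))
  ct <- 4 * (params$a2 * (outer(vb, vb) - voigt_sym_outer(bb)) +
               f4[2] * outer(v4, v4) + f6[2] * outer(v6, v6))
  # (the a2 term collects both psi2 * d2I2/dCb2 and the vanishing psi_ab
  # cross terms of the linear Mooney-Rivlin energy)

  P <- voigt_Is - outer(voigt_one, voigt_one) / 3
  vt_iso <- to_voigt(tau_iso)
  c_iso <- P %*% voigt_W %*% ct %*% voigt_W %*% P +
    (2 / 3) * tr_tau * P -
    (2 / 3) * (outer(voigt_one, vt_iso) + outer(vt_iso, voigt_one))

  # volumetric branch
  p1 <- params$k0 * (J - 1)               # dpsi_vol/dJ
  c_vol <- (J * p1 + J^2 * params$k0) * outer(voigt_one, voigt_one) -
    2 * J * p1 * voigt_Is

  (c_vol + c_iso) / J
}
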