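test_that("reference state is stress- and energy-free", {
  fr <- fiber_frame(c(1e-3, 0, 0), "CENTRAL_NT_SI_STRONG")
  p <- assign_parameters("CENTRAL_NT_SI_STRONG")
  kin <- kinematics(diag(3))
  expect_equal(strain_energy(kin, p, fr), 0)
  expect_equal(cauchy_stress(kin, p, fr), matrix(0, 3, 3))
  iv <- invariants(kin, fr)
  expect_equal(iv$I1, 3)
  expect_equal(iv$I2, 3)
  expect_equal(iv$I4, 1)
  expect_equal(iv$I6, 1)
})

test_that("non-positive det(F) is rejected", {
  expect_error(kinematics(diag(c(1, 1, -1))), "non-positive")
  expect_error(kinematics(diag(c(1, 1, 0))), "non-positive")
})

test_that("pure dilation loads only the volumetric penalty", {
  fr <- fiber_frame(c(1e-3, 0, 0), "CENTRAL_NT_SI_STRONG")
  p <- assign_parameters("CENTRAL_NT_SI_STRONG")
  J <- 1.02
  kin <- kinematics(J^(1 / 3) * diag(3))
  sig <- cauchy_stress(kin, p, fr)
  expect_equal(sig, p$k0 * (J - 1) * diag(3), tolerance = 1e-10)
  expect_equal(strain_energy(kin, p, fr), 0.5 * p$k0 * (J - 1)^2,
               tolerance = 1e-10)
})

test_that("fiber energy at 1% isochoric fiber stretch matches the formula", {
  # lambda = 1.01 along the first family at J = 1: I4b = 1.0201 and the
  # family contributes k1/(2 k2) (exp(k2 (I4b-1)^2) - 1) to the energy
  fr <- list(m0 = c(1, 0, 0), n0 = c(0, 1, 0), active2 = FALSE)
  p <- assign_parameters("CENTRAL_NT_SI_STRONG")
  lam <- 1.01
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  kin <- kinematics(F)
  expect_equal(invariants(kin, fr)$I4, lam^2, tolerance = 1e-12)
  w <- lam^2 - 1
  fiber_term <- p$k1 / (2 * p$k2) * (exp(p$k2 * w^2) - 1)
  # hand evaluation: 125 * (exp(200 * 0.0201^2) - 1) = 10.5195 Pa
  expect_equal(fiber_term, 125 * (exp(200 * 0.0201^2) - 1),
               tolerance = 1e-12)
  expect_equal(fiber_term, 10.5195, tolerance = 1e-5)
  p_iso <- p; p_iso$k1 <- 0
  expect_equal(strain_energy(kin, p, fr) - strain_energy(kin, p_iso, fr),
               fiber_term, tolerance = 1e-10)
})

test_that("Cauchy stress matches finite differences of the energy", {
  set.seed(101)
  for (lab in kfem_zone_labels) {
    p <- assign_parameters(lab)
    fr <- fiber_frame(c(3e-3, 2e-3, 0), lab)
    for (t in 1:6) {
      F <- random_small_F()
      s <- cauchy_stress(kinematics(F), p, fr)
      s_fd <- fd_cauchy(F, p, fr)
      expect_lt(max(abs(s - s_fd)) / max(abs(s)), 1e-6)
    }
  }
})

test_that("analytic tangent matches finite differences of the stress", {
  set.seed(102)
  vidx <- keratofem:::voigt_idx
  for (lab in c("CENTRAL_NT_SI_STRONG", "LIMBUS")) {
    p <- assign_parameters(lab)
    fr <- fiber_frame(c(3e-3, 2e-3, 0), lab)
    for (t in 1:4) {
      F <- random_small_F()
      kin <- kinematics(F)
      D <- material_tangent(kin, p, fr)
      sig <- cauchy_stress(kin, p, fr)
      h <- 1e-6
      for (I in 1:6) {
        H <- matrix(0, 3, 3)
        i <- vidx[I, 1]; j <- vidx[I, 2]
        H[i, j] <- H[j, i] <- 0.5 * ifelse(i == j, 2, 1)
        dsig <- (cauchy_stress(kinematics((diag(3) + h * H) %*% F), p, fr) -
                   cauchy_stress(kinematics((diag(3) - h * H) %*% F),
                                 p, fr)) / (2 * h)
        Hv <- keratofem:::to_voigt(H) * c(1, 1, 1, 2, 2, 2)
        pred <- keratofem:::from_voigt(drop(D %*% Hv)) +
          H %*% sig + sig %*% H - sig * sum(diag(H))
        expect_lt(max(abs(dsig - pred)) / max(abs(D)), 1e-6)
      }
    }
  }
})

test_that("the fiber law is symmetric by default, tension-only on demand", {
  fr <- list(m0 = c(1, 0, 0), n0 = c(0, 1, 0), active2 = FALSE)
  p <- assign_parameters("CENTRAL_NT_SI_STRONG")
  lam <- 0.99                      # fiber contraction
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  kin <- kinematics(F)
  p_iso <- p; p_iso$k1 <- 0
  # default: compressed fibers store energy (symmetric exponential law)
  expect_gt(strain_energy(kin, p, fr) - strain_energy(kin, p_iso, fr), 0)
  # tension-only: compressed fibers drop out entirely
  expect_equal(strain_energy(kin, p, fr, tension_only = TRUE),
               strain_energy(kin, p_iso, fr, tension_only = TRUE))
  expect_equal(cauchy_stress(kin, p, fr, tension_only = TRUE),
               cauchy_stress(kin, p_iso, fr, tension_only = TRUE))
})

test_that("limbus second family is inactive", {
  p <- assign_parameters("LIMBUS")
  fr <- fiber_frame(c(5.7e-3, 0, 0), "LIMBUS")
  # stretching along the (inactive) radial direction must not add energy
  lam <- 1.05
  F <- diag(c(lam, 1, 1))          # radial n0 = (1, 0, 0) at theta = 0
  expect_equal(fr$n0, c(1, 0, 0))
  p0 <- p; p0$k1 <- 0
  kin <- kinematics(F)
  e_fib <- strain_energy(kin, p, fr) - strain_energy(kin, p0, fr)
  # only the circumferential family m0 = (0, 1, 0) contributes, and it is
  # shortened isochorically, so the single active family stores little
  fr_both <- list(m0 = fr$m0, n0 = fr$n0, active2 = TRUE)
  e_both <- strain_energy(kin, p, fr_both) - strain_energy(kin, p0, fr_both)
  expect_lt(e_fib, e_both)
})

test_that("extreme fiber stretch raises the overflow guard", {
  fr <- list(m0 = c(1, 0, 0), n0 = c(0, 1, 0), active2 = FALSE)
  p <- assign_parameters("CENTRAL_NT_SI_STRONG")
  F <- diag(c(3, 1, 1))
  expect_error(strain_energy(kinematics(F), p, fr), "overextension")
  expect_error(cauchy_stress(kinematics(F), p, fr), "overextension")
})

test_that("von Mises-style invariance: stress rotates objectively", {
  p <- assign_parameters("TRANSITION")
  fr <- fiber_frame(c(3e-3, 3e-3, 0), "TRANSITION")
  set.seed(103)
  F <- random_small_F()
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  s1 <- cauchy_stress(kinematics(Q %*% F), p, fr)
  s0 <- cauchy_stress(kinematics(F), p, fr)
  expect_equal(s1, Q %*% s0 %*% t(Q), tolerance = 1e-10)
})
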