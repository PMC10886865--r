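# The element kernels are exercised on a single hexahedron against the R
# reference constitutive functions, then the assembled system is verified
# by finite differences and on the spherical-shell oracle.

asm <- function(hex, mats, u, ..., Fpre = NULL, bbar = FALSE,
                want_tangent = FALSE, want_state = FALSE) {
  keratofem:::.asm_system(hex$nodes, u, hex$elems, mats$mat_par,
                          mats$fibers, mats$active2, Fpre, bbar, FALSE,
                          want_tangent, want_state)
}

test_that("zero displacement produces zero internal force", {
  hex <- single_hex()
  mats <- hex_materials()
  out <- asm(hex, mats, matrix(0, 8, 3))
  expect_equal(max(abs(out$fint)), 0)
})

test_that("homogeneous deformation reproduces the R constitutive state", {
  hex <- single_hex()
  mats <- hex_materials()
  H <- matrix(c(0.02, 0.01, 0, -0.005, -0.01, 0.004, 0, 0.003, 0.015), 3, 3)
  u <- hex$nodes %*% t(H)
  out <- asm(hex, mats, u, want_state = TRUE)
  F <- diag(3) + H
  fr <- list(m0 = c(1, 0, 0), n0 = c(0, 1, 0), active2 = TRUE)
  p <- assign_parameters("CENTRAL_NT_SI_STRONG")
  sig_ref <- cauchy_stress(kinematics(F), p, fr)
  for (q in 1:8) {
    expect_equal(matrix(out$Ftot[1, (q - 1) * 9 + 1:9], 3, 3), F,
                 tolerance = 1e-12)
    expect_equal(keratofem:::from_voigt(out$sigma[1, (q - 1) * 6 + 1:6]),
                 sig_ref, tolerance = 1e-10)
    expect_equal(out$J[1, q], det(F), tolerance = 1e-12)
  }
  # under B-bar the homogeneous state is unchanged (J is constant)
  outb <- asm(hex, mats, u, bbar = TRUE, want_state = TRUE)
  expect_equal(outb$sigma, out$sigma, tolerance = 1e-12)
})

test_that("a multiplicative prestress composes into the total gradient", {
  hex <- single_hex()
  mats <- hex_materials()
  Fp <- diag(3) + matrix(c(0.01, 0.002, 0, 0, -0.004, 0.001,
                           0.003, 0, 0.006), 3, 3)
  Fpre <- matrix(rep(as.vector(Fp), 8), 1, 72)
  H <- matrix(c(0.015, 0, 0.002, 0.001, -0.01, 0, 0, 0.004, 0.008), 3, 3)
  u <- hex$nodes %*% t(H)
  out <- asm(hex, mats, u, Fpre = Fpre, want_state = TRUE)
  expect_equal(matrix(out$Ftot[1, 1:9], 3, 3), (diag(3) + H) %*% Fp,
               tolerance = 1e-12)
  # u = 0 with prestress alone must produce nonzero force (not equilibrium)
  out0 <- asm(hex, mats, matrix(0, 8, 3), Fpre = Fpre)
  expect_gt(max(abs(out0$fint)), 0)
})

test_that("element tangent matches finite differences of the force", {
  set.seed(7)
  hex <- single_hex(distort = 0.05)
  mats <- hex_materials()
  u0 <- matrix(rnorm(24, sd = 2e-5), 8, 3)
  fd_err <- function(bbar) {
    out <- asm(hex, mats, u0, bbar = bbar, want_tangent = TRUE)
    K <- matrix(0, 24, 24)
    K[cbind(out$Ki, out$Kj)] <- out$Kv
    h <- 1e-9
    err <- 0
    for (d in 1:24) {
      du <- matrix(0, 8, 3)
      du[(d - 1) %/% 3 + 1, (d - 1) %% 3 + 1] <- h
      fp <- asm(hex, mats, u0 + du, bbar = bbar)$fint
      fm <- asm(hex, mats, u0 - du, bbar = bbar)$fint
      err <- max(err, max(abs((fp - fm) / (2 * h) - K[, d])))
    }
    err / max(abs(K))
  }
  # full integration: exact consistent tangent
  expect_lt(fd_err(FALSE), 1e-5)
  # mean dilatation: the tangent deliberately omits the geometric coupling
  # of the element-average terms (documented); accurate to well under 1%
  expect_lt(fd_err(TRUE), 1e-2)
})

test_that("element inversion during update is reported", {
  hex <- single_hex()
  mats <- hex_materials()
  u <- matrix(0, 8, 3)
  u[5:8, 3] <- -1.5e-3                   # collapse the top face through
  expect_error(asm(hex, mats, u), "inversion")
})

test_that("follower pressure force and load stiffness are consistent", {
  # single unit facet in the xy plane, nodes CCW seen from +z
  nodes <- rbind(c(0, 0, 0), c(1e-3, 0, 0), c(1e-3, 1e-3, 0),
                 c(0, 1e-3, 0))
  facet <- matrix(1:4, 1, 4)
  p <- 2000
  pr <- keratofem:::.asm_pressure(nodes, matrix(0, 4, 3), facet, p, TRUE)
  f <- matrix(pr$fext, ncol = 3, byrow = TRUE)
  # resultant -p * A * n with n = +z, shared equally by the four nodes
  expect_equal(colSums(f), c(0, 0, -p * 1e-6), tolerance = 1e-12)
  expect_equal(f[, 3], rep(-p * 1e-6 / 4, 4), tolerance = 1e-12)
  # load stiffness vs finite differences, on a warped configuration
  set.seed(11)
  u0 <- matrix(rnorm(12, sd = 1e-4), 4, 3)
  pr0 <- keratofem:::.asm_pressure(nodes, u0, facet, p, TRUE)
  K <- matrix(0, 12, 12)
  K[cbind(pr0$Ki, pr0$Kj)] <- pr0$Kv
  h <- 1e-9
  for (d in 1:12) {
    du <- matrix(0, 4, 3)
    du[(d - 1) %/% 3 + 1, (d - 1) %% 3 + 1] <- h
    fp <- keratofem:::.asm_pressure(nodes, u0 + du, facet, p, FALSE)$fext
    fm <- keratofem:::.asm_pressure(nodes, u0 - du, facet, p, FALSE)$fext
    expect_lt(max(abs((fp - fm) / (2 * h) - K[, d])), 1e-4 * max(abs(K)))
  }
  # a degenerate (collapsed) facet is rejected
  ubad <- -nodes
  expect_error(keratofem:::.asm_pressure(nodes, ubad, facet, p, FALSE),
               "degenerate")
})

test_that("embedded forward solve converges and inflates anteriorly", {
  mesh <- tiny_mesh()
  mats <- material_assignment(mesh)
  bc <- build_bc(mesh, "embedded")
  st <- cached("state_embedded_15", solve_forward(mesh, mats, bc, 15))
  expect_s3_class(st, "kfem_state")
  # apex moves toward -z (anteriorly, against the IOP direction)
  expect_lt(st$u[mesh$apex_ip, 3], -1e-4)
  expect_lt(abs(st$u[mesh$apex_ip, 1]), 1e-8)
  # rim nodes are fixed
  expect_equal(max(abs(st$u[unlist(rim_sections(mesh)), ])), 0)
  # all substeps converged; last Newton residual tiny
  expect_identical(max(st$log$substep), 10L)
  last <- st$log[nrow(st$log), ]
  expect_lt(last$residual, 1e-8 * last$reference + 1e-10)
  # quadratic-ish convergence: each substep ends after few iterations
  its <- tapply(st$log$iter, st$log$substep, max)
  expect_true(all(its <= 8))
  # Jacobians stay positive and near unity (quasi-incompressible)
  expect_true(all(st$Jgp > 0.97 & st$Jgp < 1.03))
})

test_that("pressure scales the response monotonically", {
  mesh <- tiny_mesh()
  mats <- material_assignment(mesh)
  bc <- build_bc(mesh, "embedded")
  st15 <- cached("state_embedded_15", solve_forward(mesh, mats, bc, 15))
  st5 <- solve_forward(mesh, mats, bc, 5,
                       control = solver_control(substeps = 4))
  expect_lt(max(abs(st5$u)), max(abs(st15$u)))
  expect_gt(max(abs(st5$u)), 0)
  # zero pressure is the trivial solution
  st0 <- solve_forward(mesh, mats, bc, 0,
                       control = solver_control(substeps = 1))
  expect_equal(max(abs(st0$u)), 0)
})

test_that("pivoting sections rotate rigidly about the section centroid", {
  mesh <- tiny_mesh()
  mats <- material_assignment(mesh)
  bc <- build_bc(mesh, "pivoting")
  st <- cached("state_pivoting_15",
               solve_forward(mesh, mats, bc, 15))
  expect_s3_class(st, "kfem_state")
  # at least some rotation happened
  expect_gt(max(abs(st$theta)), 1e-5)
  for (s in seq_along(bc$sections)) {
    ids <- bc$sections[[s]]
    X <- mesh$nodes[ids, ]
    x <- st$x[ids, ]
    cen <- bc$centroid[[s]]
    # distances to the (fixed) centroid are preserved: rigid rotation
    expect_equal(sqrt(rowSums(sweep(x, 2, cen)^2)),
                 sqrt(rowSums(sweep(X, 2, cen)^2)), tolerance = 1e-12)
    # and the motion is the recorded rotation about the section axis
    R <- keratofem:::axis_rotation(bc$axis[[s]], st$theta[s])
    xr <- sweep(sweep(X, 2, cen) %*% t(R), 2, cen, `+`)
    expect_equal(x, xr, tolerance = 1e-12)
  }
  # pivoting relaxes the clamped rim: different interior solution
  st_emb <- cached("state_embedded_15", solve_forward(
    mesh, mats, build_bc(mesh, "embedded"), 15))
  expect_gt(max(abs(st$u - st_emb$u)), 1e-6)
})

test_that("spherical cap with roller support matches the 1-D reference", {
  fix <- spherical_cap_fixture()
  ref <- cached("sphere_ref",
                sphere_inflation_reference(fix$Ri, fix$Ro, 15 * 133.322))
  # the 1-D reference itself satisfies global (hemisphere) equilibrium
  r <- ref$r; st <- ref$sigma_tt
  lhs <- 15 * 133.322 * pi * r[1]^2
  rhs <- 2 * pi * sum(diff(r) * (st[-1] * r[-1] +
                                   st[-length(r)] * r[-length(r)]) / 2)
  expect_lt(abs(rhs - lhs) / lhs, 1e-6)
  expect_lt(abs(ref$srr_outer), 1e-6 * 15 * 133.322)

  u_coarse <- cached("sphere_cap_coarse", sphere_solve_cap(fix, mesh_spec()))
  u_fine <- cached("sphere_cap_fine", sphere_solve_cap(fix, fix$mesh))
  err <- function(u) max(abs(c(u["outer"] - ref$u_outer,
                               u["inner"] - ref$u_inner)) /
                           abs(c(ref$u_outer, ref$u_inner)))
  expect_lt(err(u_fine), 0.02)
  expect_lt(err(u_fine), err(u_coarse))   # converges under refinement
})
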