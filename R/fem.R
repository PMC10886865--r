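# Nonlinear elastostatics on the corneal mesh: zone-wise material
# assignment, limbus boundary conditions as multipoint constraints
# (master-slave elimination), follower IOP loading, and incremental Newton
# with load substeps.

MMHG_PA <- 133.322

#' Solver control parameters
#'
#' @param substeps Equal pressure increments of the incremental loading
#'   (default 10).
#' @param rtol Relative residual tolerance of the Newton loop.
#' @param maxit Maximum Newton iterations per substep.
#' @param atol Absolute residual floor (N).
#' @param bbar Mean-dilatation (B-bar) treatment of the hexahedra; switch to
#'   `FALSE` for full integration diagnostics.  With B-bar the assembled
#'   tangent omits the geometric coupling of the element-average dilatation
#'   terms (a standard simplification, accurate to well under 1%); the
#'   full-integration tangent is exact.
#' @param tension_only Fiber families active only in extension.
#' @return A list of class `kfem_control`.
#' @export
solver_control <- function(substeps = 10, rtol = 1e-8, maxit = 50,
                           atol = 1e-12, bbar = TRUE, tension_only = FALSE) {
  stopifnot(substeps >= 1, rtol > 0, maxit >= 1)
  structure(list(substeps = as.integer(substeps), rtol = rtol,
                 maxit = as.integer(maxit), atol = atol, bbar = bbar,
                 tension_only = tension_only),
            class = "kfem_control")
}

#' Zone-wise material assignment for a mesh
#'
#' Maps every element's zone label to its parameter row and fiber frame
#' (computed once from the element centroids of the measured mesh; fiber
#' directions are held constant afterwards, in particular throughout the
#' inverse iterations).
#'
#' @param mesh A `kfem_mesh`.
#' @param k0 Bulk factor (Pa).
#' @param overrides Optional named list of per-zone parameter override lists,
#'   e.g. `list(LIMBUS = list(k1 = 4e4))`.
#' @param fiber_fun Optional `function(centroid, label)` replacing
#'   [fiber_frame()].
#' @return A `kfem_materials` with per-element parameter and fiber arrays.
#' @export
material_assignment <- function(mesh, k0 = 5.5e6, overrides = NULL,
                                fiber_fun = fiber_frame) {
  E <- nrow(mesh$elems)
  mat_par <- matrix(0, E, 5)
  fibers <- matrix(0, E, 6)
  active2 <- integer(E)
  cent <- element_centroids(mesh)
  for (e in seq_len(E)) {
    z <- mesh$zone[e]
    p <- assign_parameters(z, k0 = k0, overrides = overrides[[z]])
    mat_par[e, ] <- c(p$a1, p$a2, p$k1, p$k2, p$k0)
    fr <- fiber_fun(cent[e, ], z)
    fibers[e, ] <- c(fr$m0, fr$n0)
    active2[e] <- as.integer(isTRUE(fr$active2) && p$n_families == 2L)
  }
  structure(list(mat_par = mat_par, fibers = fibers, active2 = active2,
                 zone = mesh$zone),
            class = "kfem_materials")
}

element_centroids <- function(mesh, nodes = mesh$nodes) {
  E <- nrow(mesh$elems)
  cent <- matrix(0, E, 3)
  for (a in 1:8) cent <- cent + nodes[mesh$elems[, a], , drop = FALSE]
  cent / 8
}

#' Build limbus boundary conditions
#'
#' `embedded`: every rim-section node is fully fixed (clamped
#' corneo-scleral interface).  `pivoting`: each rim cross-section moves as a
#' rigid body slaved to a master node at its mid-thickness centroid; the
#' master's translations and the rotations about the radial and meridional
#' axes are fixed, leaving one free rotation about the local circumferential
#' tangent.  `radial_roller` constrains each rim node to move along its ray
#' from a given center (a symmetry condition used for spherical-shell
#' verification problems).
#'
#' @param mesh A `kfem_mesh`.
#' @param mode `"embedded"`, `"pivoting"` or `"radial_roller"`.
#' @param center Ray origin for `radial_roller` (m).
#' @return A `kfem_bc`.
#' @export
build_bc <- function(mesh, mode = c("embedded", "pivoting", "radial_roller"),
                     center = NULL) {
  mode <- match.arg(mode)
  sections <- rim_sections(mesh)
  if (!length(sections) || !length(sections[[1]]))
    stop("mesh has an empty limbus rim")
  rim_nodes <- unlist(sections)
  bc <- list(mode = mode, sections = sections, rim_nodes = rim_nodes)
  if (mode == "pivoting") {
    bc$centroid <- lapply(sections, function(ids)
      colMeans(mesh$nodes[ids, , drop = FALSE]))
    bc$axis <- lapply(seq_along(sections), function(s) {
      cen <- bc$centroid[[s]]
      th <- atan2(cen[2], cen[1])
      c(-sin(th), cos(th), 0)            # circumferential tangent
    })
  }
  if (mode == "radial_roller") {
    if (is.null(center)) stop("radial_roller needs a ray center")
    bc$center <- center
    bc$dirs <- lapply(rim_nodes, function(n) {
      d <- mesh$nodes[n, ] - center
      d / sqrt(sum(d^2))
    })
  }
  structure(bc, class = "kfem_bc")
}

# re-evaluate the geometric data of a BC (section centroids, axes, ray
# directions) on a replacement reference configuration, so the same
# constraint definition follows the reference geometry during the inverse
# iterations
bc_localize <- function(bc, nodes) {
  if (bc$mode == "pivoting") {
    bc$centroid <- lapply(bc$sections, function(ids)
      colMeans(nodes[ids, , drop = FALSE]))
    bc$axis <- lapply(bc$centroid, function(cen) {
      th <- atan2(cen[2], cen[1])
      c(-sin(th), cos(th), 0)
    })
  } else if (bc$mode == "radial_roller") {
    bc$dirs <- lapply(bc$rim_nodes, function(n) {
      d <- nodes[n, ] - bc$center
      d / sqrt(sum(d^2))
    })
  }
  bc
}

# rotation matrix about unit axis by angle
axis_rotation <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Build the master-slave transformation u = T q for the current constraint
# state.  Returns T (sparse 3N x nred), index bookkeeping, and the number of
# section DOFs.  For pivoting the columns of the section DOFs are evaluated
# at the sections' current (rotated) positions.
build_transform <- function(mesh, bc, X, theta = NULL) {
  N <- nrow(X)
  ndof <- 3L * N
  rim <- unique(bc$rim_nodes)
  rim_dofs <- as.vector(t(outer(3 * (rim - 1), 1:3, `+`)))
  free_dofs <- setdiff(seq_len(ndof), rim_dofs)
  nf <- length(free_dofs)

  ti <- free_dofs; tj <- seq_len(nf); tv <- rep(1, nf)
  ncol_extra <- 0L
  if (bc$mode == "pivoting") {
    ns <- length(bc$sections)
    ncol_extra <- ns
    for (s in seq_len(ns)) {
      ids <- bc$sections[[s]]
      cen <- bc$centroid[[s]]; ax <- bc$axis[[s]]
      R <- axis_rotation(ax, if (is.null(theta)) 0 else theta[s])
      for (n in ids) {
        xcur <- cen + drop(R %*% (X[n, ] - cen))
        lever <- c(ax[2] * (xcur[3] - cen[3]) - ax[3] * (xcur[2] - cen[2]),
                   ax[3] * (xcur[1] - cen[1]) - ax[1] * (xcur[3] - cen[3]),
                   ax[1] * (xcur[2] - cen[2]) - ax[2] * (xcur[1] - cen[1]))
        ti <- c(ti, 3 * (n - 1) + 1:3)
        tj <- c(tj, rep(nf + s, 3))
        tv <- c(tv, lever)
      }
    }
  } else if (bc$mode == "radial_roller") {
    nr <- length(bc$rim_nodes)
    ncol_extra <- nr
    for (k in seq_len(nr)) {
      n <- bc$rim_nodes[k]
      ti <- c(ti, 3 * (n - 1) + 1:3)
      tj <- c(tj, rep(nf + k, 3))
      tv <- c(tv, bc$dirs[[k]])
    }
  }
  T <- Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                            dims = c(ndof, nf + ncol_extra))
  list(T = T, free_dofs = free_dofs, nf = nf, ncol_extra = ncol_extra)
}

# apply a reduced-space increment dq to (u, theta); pivoting sections are
# updated by exact rigid rotation so the MPC holds exactly
apply_increment <- function(mesh, bc, u, theta, tr, dq, scale = 1,
                            X = mesh$nodes) {
  du_free <- scale * dq[seq_len(tr$nf)]
  uv <- as.vector(t(u))
  uv[tr$free_dofs] <- uv[tr$free_dofs] + du_free
  u <- matrix(uv, ncol = 3, byrow = TRUE)
  if (bc$mode == "pivoting") {
    theta <- theta + scale * dq[tr$nf + seq_len(tr$ncol_extra)]
    for (s in seq_along(bc$sections)) {
      ids <- bc$sections[[s]]
      cen <- bc$centroid[[s]]
      R <- axis_rotation(bc$axis[[s]], theta[s])
      for (n in ids) {
        xnew <- cen + drop(R %*% (X[n, ] - cen))
        u[n, ] <- xnew - X[n, ]
      }
    }
  } else if (bc$mode == "radial_roller") {
    dq_r <- scale * dq[tr$nf + seq_len(tr$ncol_extra)]
    for (k in seq_along(bc$rim_nodes)) {
      n <- bc$rim_nodes[k]
      u[n, ] <- u[n, ] + dq_r[k] * bc$dirs[[k]]
    }
  }
  list(u = u, theta = theta)
}

#' External follower-pressure nodal forces
#'
#' Integrates the intraocular pressure over the current (deformed) posterior
#' facets; the load follows the facet normals as the surface deforms.
#'
#' @param mesh A `kfem_mesh`.
#' @param u `N x 3` nodal displacements (m).
#' @param iop_pa Pressure (Pa).
#' @param nodes Optional replacement reference coordinates.
#' @return Length-`3N` force vector (N), components interleaved per node.
#' @export
external_pressure_forces <- function(mesh, u = NULL, iop_pa,
                                     nodes = mesh$nodes) {
  if (is.null(u)) u <- matrix(0, nrow(nodes), 3)
  out <- .asm_pressure(nodes, u, mesh$facets_post, iop_pa, FALSE)
  out$fext
}

#' Solve the forward (inflation) problem
#'
#' Incremental loading of the corneal model with the IOP applied as a
#' follower pressure in `control$substeps` equal increments, full Newton
#' with the consistent tangent (including the pressure load stiffness) on
#' the MPC-reduced system.  An optional per-Gauss-point prestress
#' deformation gradient `F_pre` enters multiplicatively:
#' `F_total = F_inc(u) . F_pre`.
#'
#' @param mesh A `kfem_mesh`.
#' @param materials A `kfem_materials`.
#' @param bc A `kfem_bc`.
#' @param iop_mmhg Intraocular pressure (mmHg; converted at 133.322 Pa/mmHg).
#' @param F_pre Optional `E x 72` matrix of per-Gauss-point prestress
#'   deformation gradients (column-major 3x3 per point).
#' @param nodes Optional replacement reference node coordinates (the inverse
#'   methods iterate on these).  Geometric BC data (section centroids, ray
#'   directions) are re-evaluated on these coordinates.
#' @param control A `kfem_control`.
#' @param warm Optional warm start: a previous `kfem_state` (or a list with
#'   `u` and `theta`) whose displacements seed the Newton loop.  Callers
#'   typically combine this with `control = solver_control(substeps = 1)`
#'   when the seed is close to the solution.
#' @return A `kfem_state`: displacements `u`, deformed coordinates `x`,
#'   Gauss-point deformation gradients / Cauchy stresses / Jacobians, and a
#'   convergence log.
#' @export
solve_forward <- function(mesh, materials, bc, iop_mmhg, F_pre = NULL,
                          nodes = mesh$nodes, control = solver_control(),
                          warm = NULL) {
  N <- nrow(nodes)
  p_total <- iop_mmhg * MMHG_PA
  bc <- bc_localize(bc, nodes)
  u <- matrix(0, N, 3)
  theta <- rep(0, length(bc$sections))
  if (!is.null(warm)) {
    u <- warm$u
    if (!is.null(warm$theta) && length(warm$theta) == length(theta))
      theta <- warm$theta
    # project the seed onto the current constraint manifold (the rim rows
    # of a seed from a slightly different reference are not exactly
    # consistent with theta on this one)
    tr0 <- build_transform(mesh, bc, nodes, theta)
    u <- apply_increment(mesh, bc, u, theta,
                         tr0, numeric(tr0$nf + tr0$ncol_extra),
                         X = nodes)$u
  }
  log <- list()

  for (s in seq_len(control$substeps)) {
    p_s <- p_total * s / control$substeps
    conv <- FALSE
    res_prev <- Inf
    for (it in 0:control$maxit) {
      sys <- .asm_system(nodes, u, mesh$elems, materials$mat_par,
                         materials$fibers, materials$active2, F_pre,
                         control$bbar, control$tension_only, TRUE, FALSE)
      pr <- .asm_pressure(nodes, u, mesh$facets_post, p_s, TRUE)
      r <- sys$fint - pr$fext
      tr <- build_transform(mesh, bc, nodes, theta)
      rr <- as.numeric(Matrix::crossprod(tr$T, r))
      fr <- as.numeric(Matrix::crossprod(tr$T, pr$fext))
      res <- sqrt(sum(rr^2))
      ref <- max(sqrt(sum(fr^2)), control$atol)
      log[[length(log) + 1]] <- data.frame(substep = s, iter = it,
                                           residual = res, reference = ref)
      if (res <= control$rtol * ref + control$atol) { conv <- TRUE; break }
      if (it == control$maxit) break
      K <- Matrix::sparseMatrix(i = c(sys$Ki, pr$Ki), j = c(sys$Kj, pr$Kj),
                                x = c(sys$Kv, -pr$Kv), dims = c(3 * N, 3 * N))
      Kred <- Matrix::crossprod(tr$T, K %*% tr$T)
      # the reduced tangent is symmetric (follower-pressure load stiffness
      # is symmetric for a wetted surface with constrained boundary); use a
      # sparse Cholesky and fall back to LU if the factorization fails
      Ks <- Matrix::forceSymmetric((Kred + Matrix::t(Kred)) / 2)
      dq <- tryCatch(
        withCallingHandlers(
          as.numeric(Matrix::solve(
            Matrix::Cholesky(Ks, LDL = FALSE, perm = TRUE), -rr)),
          # an indefinite tangent (e.g. on a warm start far from the
          # solution) only warns in CHOLMOD; escalate so the LU path is used
          warning = function(w) stop(conditionMessage(w))),
        error = function(e) tryCatch(as.numeric(Matrix::solve(Kred, -rr)),
                     error = function(e)
                       stop("linear solve failed (possibly indefinite ",
                            "tangent) at substep ", s, ", iteration ", it,
                            ": ", conditionMessage(e))))
      # step halving guard against element inversion / wild steps
      scale <- 1
      for (h in 1:6) {
        cand <- apply_increment(mesh, bc, u, theta, tr, dq, scale,
                                X = nodes)
        ok <- tryCatch({
          chk <- .asm_system(nodes, cand$u, mesh$elems, materials$mat_par,
                             materials$fibers, materials$active2, F_pre,
                             control$bbar, control$tension_only, FALSE, FALSE)
          all(is.finite(chk$fint))
        }, error = function(e) FALSE)
        if (ok) break
        scale <- scale / 2
        if (h == 6)
          stop("Newton step failed repeatedly (element inversion) at ",
               "substep ", s, ", iteration ", it)
      }
      u <- cand$u; theta <- cand$theta
      res_prev <- res
    }
    if (!conv) {
      stop("Newton did not converge at substep ", s, " (last residual ",
           signif(res, 4), ", reference ", signif(ref, 4), ")")
    }
  }

  st <- .asm_system(nodes, u, mesh$elems, materials$mat_par,
                    materials$fibers, materials$active2, F_pre,
                    control$bbar, control$tension_only, FALSE, TRUE)
  structure(list(u = u, nodes = nodes, x = nodes + u,
                 theta = theta, iop_mmhg = iop_mmhg,
                 Fgp = st$Ftot, sigma_gp = st$sigma, Jgp = st$J,
                 fint = st$fint,
                 log = do.call(rbind, log),
                 control = control),
            class = "kfem_state")
}

#' @export
print.kfem_state <- function(x, ...) {
  umag <- sqrt(rowSums(x$u^2))
  cat("<kfem_state> IOP", x$iop_mmhg, "mmHg;",
      nrow(x$u), "nodes;",
      "max |u| =", format(max(umag)), "m;",
      max(x$log$substep), "substeps,",
      nrow(x$log), "Newton iterations total\n")
  invisible(x)
}
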