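test_that("mesh spec validates its arguments", {
  expect_error(mesh_spec(n_angular = 3), "n_angular")
  expect_error(mesh_spec(n_layers = 0), "n_layers")
  expect_s3_class(mesh_spec(), "kfem_meshspec")
})

test_that("element count matches the closed-form formula", {
  mesh <- tiny_mesh()
  expect_identical(nrow(mesh$elems), count_elements(mesh_spec(), n_bands = 6))
  expect_identical(nrow(mesh$elems), 512L)
  ms <- mesh_spec(n_angular = 4, n_transition = 2,
                  ring_divisions = rep(2L, 6))
  expect_identical(count_elements(ms), 2048L)
  expect_error(generate_mesh(default_cornea(), segmentation_spec(),
                             mesh_spec(ring_divisions = rep(1L, 3))),
               "length")
})

test_that("all element Jacobians are positive and volume is consistent", {
  mesh <- tiny_mesh()
  expect_true(all(keratofem:::element_min_jacobians(mesh) > 0))
  vol <- element_volumes(mesh)
  expect_true(all(vol > 0))
  # total volume approximates the integral of the thickness over the disc
  g <- default_cornea()
  rr <- seq(0, 6e-3, length.out = 400)
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  thick <- vapply(th, function(t) g$z_post(rr, t) - g$z_ant(rr, t),
                  numeric(length(rr)))
  integrand <- rowMeans(thick) * rr
  vol_ref <- 2 * pi * sum((integrand[-1] + integrand[-400]) / 2 * diff(rr))
  expect_lt(abs(sum(vol) - vol_ref) / vol_ref, 0.05)
})

test_that("the structured layout conforms to rings and sectors", {
  mesh <- tiny_mesh()
  # every ring radius and the outer boundary is a mesh circle
  expect_true(all(vapply(c(1, 2, 3, 4, 5, 5.5, 6) * 1e-3, function(rr)
    any(abs(mesh$circle_radii - rr) < 1e-12), TRUE)))
  # sector-boundary meridians are angular stations
  hw <- 22.5 * pi / 180
  merid <- (hw + (0:7) * 2 * hw) %% (2 * pi)
  expect_true(all(vapply(merid, function(m)
    any(abs(mesh$station_angles - m) < 1e-12), TRUE)))
  # element zone tags match direct classification of the centroids
  cent <- keratofem:::element_centroids(mesh)
  expect_identical(classify_point(cent, mesh$spec)$zone, mesh$zone)
  expect_true(all(kfem_zone_labels %in% unique(mesh$zone)))
})

test_that("nodes interpolate the anterior and posterior surfaces", {
  mesh <- tiny_mesh()
  g <- default_cornea()
  n_ip <- mesh$n_ip
  interior <- which(mesh$inplane$rho < 5.9e-3)   # rim columns are tilted
  ant <- mesh$nodes[interior, ]
  post <- mesh$nodes[mesh$n_layers * n_ip + interior, ]
  expect_equal(ant[, 3], g$z_ant(mesh$inplane$rho[interior],
                                 mesh$inplane$theta[interior]),
               tolerance = 1e-12)
  expect_equal(post[, 3], g$z_post(mesh$inplane$rho[interior],
                                   mesh$inplane$theta[interior]),
               tolerance = 1e-12)
  # apex node sits at the origin on the anterior surface
  expect_equal(unname(mesh$nodes[mesh$apex_ip, ]), c(0, 0, 0))
})

test_that("posterior facets have outward (+z) normals covering the surface", {
  mesh <- tiny_mesh()
  av <- keratofem:::facet_vector_areas(mesh$nodes, mesh$facets_post)
  expect_true(all(av[, 3] > 0))
  # the projected (z) total equals the shoelace area of the posterior rim
  # polygon exactly (interior edge contributions cancel)
  rim_post <- vapply(rim_sections(mesh), function(s) s[length(s)], 1L)
  P <- mesh$nodes[rim_post, 1:2]
  P <- P[order(atan2(P[, 2], P[, 1])), ]
  n <- nrow(P)
  shoe <- 0.5 * abs(sum(P[, 1] * P[c(2:n, 1), 2] -
                          P[c(2:n, 1), 1] * P[, 2]))
  expect_equal(sum(av[, 3]), shoe, tolerance = 1e-9)
})

test_that("rim sections span every station through the thickness", {
  mesh <- tiny_mesh()
  rs <- rim_sections(mesh)
  expect_length(rs, 16)                   # 8 * n_angular stations
  for (s in rs) expect_length(s, mesh$n_layers + 1)
  ids <- unlist(rs)
  expect_identical(anyDuplicated(ids), 0L)
  rho <- sqrt(rowSums(mesh$nodes[ids, 1:2]^2))
  expect_true(all(rho > 5.5e-3))
})

test_that("rim ray alignment places rim columns on center rays", {
  fix <- spherical_cap_fixture()
  mesh <- generate_mesh(fix$geometry, segmentation_spec(), mesh_spec(),
                        rim_ray_center = fix$center)
  for (sec in rim_sections(mesh)) {
    P <- sweep(mesh$nodes[sec, ], 2, fix$center)
    d <- P / sqrt(rowSums(P^2))
    # all nodes of a section share one ray direction
    expect_lt(max(abs(sweep(d, 2, d[1, ]))), 1e-6)
    # and sit on their spherical surfaces
    r <- sqrt(rowSums(P^2))
    expect_equal(r[1], fix$Ro, tolerance = 1e-9)
    expect_equal(r[length(r)], fix$Ri, tolerance = 1e-9)
  }
})

test_that("degenerate geometry is reported as a meshing failure", {
  # surfaces that cross locally (posterior dipping under the anterior)
  # must be caught as non-positive element Jacobians
  g <- default_cornea()
  ant <- g$z_ant
  g$z_post <- function(r, theta)
    ant(r, theta) - 2e-4 * exp(-((r - 3e-3) / 8e-4)^2)
  expect_error(generate_mesh(g, segmentation_spec(), mesh_spec()),
               "meshing failure|inversion|Jacobian")
})
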