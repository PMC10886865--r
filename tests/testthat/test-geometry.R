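test_that("biconic sag reduces to the spherical sag for Q = 0", {
  p <- biconic_params(7.8e-3, 7.8e-3, 0, 0)
  r <- c(0, 1e-3, 2.5e-3, 5e-3)
  expect_equal(biconic_sag(p, r, 0), 7.8e-3 - sqrt(7.8e-3^2 - r^2),
               tolerance = 1e-12)
})

test_that("biconic sag errors outside the conic domain", {
  p <- biconic_params(2e-3, 2e-3, 0, 0)
  expect_error(biconic_sag(p, 2.5e-3, 0), "undefined")
})

test_that("default cornea has the nominal central thickness and geometry", {
  g <- default_cornea()
  expect_s3_class(g, "kfem_geometry")
  expect_equal(g$central_thickness, 5.5e-4)
  expect_equal(g$z_ant(0, 0), 0)
  expect_equal(g$z_post(0, 0), 5.5e-4)
  expect_equal(g$outer_radius, 6e-3)
  expect_equal(g$limbus_angle, 40 * pi / 180)
  th <- keratofem:::thickness_grid(g)
  expect_true(all(th$thickness > 0))
  # peripheral thickness exceeds central thickness (posterior steeper)
  expect_gt(g$z_post(4e-3, 0) - g$z_ant(4e-3, 0), 5.5e-4)
})

test_that("cone severity grades are strictly monotone", {
  grades <- c("G1", "G2", "G3", "G4")
  geoms <- lapply(grades, function(gr)
    default_cornea(cone = keratoconus_cone(gr)))
  kmax <- vapply(geoms, anterior_curvature_max, 0)
  k0 <- anterior_curvature_max(default_cornea())
  expect_true(all(diff(kmax) > 0))
  expect_gt(kmax[1], k0)
  tmin <- vapply(geoms, function(g)
    min(keratofem:::thickness_grid(g)$thickness), 0)
  expect_true(all(diff(tmin) < 0))
  expect_lt(tmin[1], 5.5e-4)
})

test_that("cone perturbation is localized at its center", {
  cone <- keratoconus_cone("G3")
  g <- default_cornea(cone = cone)
  g0 <- default_cornea()
  x0 <- cone$r0 * cos(cone$theta0); y0 <- cone$r0 * sin(cone$theta0)
  r0 <- sqrt(x0^2 + y0^2); th0 <- atan2(y0, x0)
  # full amplitude at the cone center, negligible far away
  expect_equal(g$z_ant(r0, th0) - g0$z_ant(r0, th0), -cone$amplitude,
               tolerance = 1e-9)
  expect_lt(abs(g$z_ant(5.8e-3, th0 + pi) - g0$z_ant(5.8e-3, th0 + pi)),
            cone$amplitude * 1e-2)
})

test_that("invalid thinning fractions are rejected", {
  expect_error(cone_perturbation(amplitude = 1e-4, thinning = 1.2),
               "thinning")
  expect_error(cone_perturbation(amplitude = -1e-4), "amplitude")
})

test_that("surfaces that cross peripherally are rejected as infeasible", {
  expect_error(
    make_cornea(biconic_params(6.5e-3, 6.5e-3, role = "anterior"),
                biconic_params(2e-2, 2e-2, role = "posterior",
                               apex_offset = 1e-4)),
    "infeasible")
})

test_that("posterior apex offset must exceed the anterior's", {
  expect_error(
    make_cornea(biconic_params(7.8e-3, 7.8e-3, role = "anterior"),
                biconic_params(6.5e-3, 6.5e-3, role = "posterior",
                               apex_offset = 0)),
    "infeasible")
})

test_that("topography CSV round trip is exact", {
  g <- default_cornea(cone = keratoconus_cone("G2"))
  topo <- to_topography(g, n_meridians = 16, n_radial = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_topography(topo, f)
  back <- read_topography(f)
  expect_equal(back$theta, topo$theta)
  expect_equal(back$r, topo$r)
  expect_equal(back$z_ant, topo$z_ant, ignore_attr = TRUE)
  expect_equal(back$z_post, topo$z_post, ignore_attr = TRUE)
  hdr <- readLines(f, n = 1)
  expect_identical(hdr, "theta_rad,r_m,z_ant_m,z_post_m")
})

test_that("reconstruction from a dense topography reproduces the surface", {
  g <- default_cornea(cone = keratoconus_cone("G1"))
  topo <- to_topography(g, n_meridians = 48, n_radial = 40)
  g2 <- from_topography(topo)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  r <- seq(0.2e-3, 5.8e-3, length.out = 21)
  grid <- expand.grid(r = r, th = th)
  err_a <- max(abs(g2$z_ant(grid$r, grid$th) - g$z_ant(grid$r, grid$th)))
  err_p <- max(abs(g2$z_post(grid$r, grid$th) - g$z_post(grid$r, grid$th)))
  expect_lt(err_a, 1e-6)   # sub-micron surface reconstruction
  expect_lt(err_p, 1e-6)
  # interpolates the grid knots themselves much more tightly
  expect_lt(max(abs(g2$z_ant(topo$r[5], topo$theta) - topo$z_ant[, 5])),
            1e-12)
})

test_that("missing topography cells are filled by angular interpolation", {
  g <- default_cornea()
  topo <- to_topography(g, n_meridians = 24, n_radial = 16)
  full <- topo
  drop <- cbind(c(3, 7, 20), c(4, 9, 12))
  topo$z_ant[drop] <- NA
  topo$z_post[drop] <- NA
  g2 <- from_topography(topo)
  gf <- from_topography(full)
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  expect_lt(max(abs(g2$z_ant(3e-3, th) - gf$z_ant(3e-3, th))), 5e-7)
})

test_that("non-rectangular topography input is rejected", {
  g <- default_cornea()
  topo <- to_topography(g, n_meridians = 12, n_radial = 10)
  broken <- topo
  broken$z_ant <- broken$z_ant[, -1]
  expect_error(from_topography(broken), "rectangular")
  f <- withr::local_tempfile(fileext = ".csv")
  write_topography(topo, f)
  df <- utils::read.csv(f)
  utils::write.csv(df[-1, ], f, row.names = FALSE)
  expect_error(read_topography(f), "rectangular")
})
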