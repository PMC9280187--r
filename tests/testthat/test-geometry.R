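test_that("core and shell measures match closed forms", {
  geom <- ref_geom()
  # reference cross-section areas, 4 d.p.
  expect_equal(round(core_volume(geom), 4), 1.5175)
  expect_equal(round(shell_volume(geom), 4), 0.2971)
  # unit-radius disk
  expect_equal(core_volume(particle_geometry(d0 = 2, d1 = 3)), pi)
  # 3D sphere against a direct one-line evaluation
  g3 <- particle_geometry(dimension = "3D")
  expect_equal(core_volume(g3), 4 / 3 * pi * 0.695^3, tolerance = 1e-14)
  # shell measure vanishes as d1 -> d0
  thin <- particle_geometry(d0 = 1.39, d1 = 1.39 + 1e-9)
  expect_lt(shell_volume(thin), 1e-8)
  expect_gt(shell_volume(thin), 0)
  # annulus area by hand
  expect_equal(shell_volume(particle_geometry(d0 = 1, d1 = 2)),
               pi * (1^2 - 0.5^2))
})

test_that("geometry validation rejects inconsistent inputs", {
  expect_error(particle_geometry(d0 = 2, d1 = 1.5), "larger than 'd0'")
  expect_error(particle_geometry(d0 = -1), "positive")
  expect_error(particle_geometry(eccentricity = 1), "\\[0, 1\\)")
  expect_error(particle_geometry(shape = "ellipse", eccentricity = 0.5,
                                 dimension = "3D"), "2D")
})

test_that("elliptical perturbations preserve layer areas", {
  geom <- ref_geom()
  # lambda = 0 recovers the circle
  e0 <- make_ellipse(geom, 0)
  expect_equal(e0$a0, 0.695)
  expect_equal(e0$b0, 0.695)
  expect_equal(e0$a1, 0.76)
  expect_equal(e0$b1, 0.76)
  # lambda = 0.6: closed-form axis ratio and area constraint
  e6 <- make_ellipse(geom, 0.6)
  expect_equal(e6$b0 / e6$a0, sqrt(1 - 0.6^2), tolerance = 1e-12)
  expect_equal(e6$a0 * e6$b0, 0.695^2, tolerance = 1e-12)
  expect_equal(round(pi * e6$a0 * e6$b0, 4), 1.5175)
  # area preservation across the eccentricity range
  for (lam in seq(0, 0.9, by = 0.1)) {
    el <- make_ellipse(geom, lam)
    expect_equal(pi * el$a0 * el$b0, core_volume(geom), tolerance = 1e-12)
    expect_equal(pi * (el$a1 * el$b1 - el$a0 * el$b0), shell_volume(geom),
                 tolerance = 1e-12)
    # outer strictly contains core
    expect_gt(el$a1, el$a0)
    expect_gt(el$b1, el$b0)
  }
  expect_error(make_ellipse(geom, 1), "eccentricity")
})

test_that("radial grid hits the interface exactly and conserves measure", {
  geom <- ref_geom()
  g <- build_radial_grid(geom, 4, 4)
  expect_length(g$r, 9)
  expect_identical(g$r[g$interface_index], 0.695)
  expect_identical(g$r[length(g$r)], 0.76)
  expect_true(all(diff(g$r) > 0))
  # control volumes partition the layers
  expect_equal(sum(g$measure), core_volume(geom) + shell_volume(geom),
               tolerance = 1e-12)
  expect_equal(sum(g$measure_core), core_volume(geom), tolerance = 1e-12)
  expect_equal(sum(g$measure_shell), shell_volume(geom), tolerance = 1e-12)
  # refinement leaves totals and key radii invariant
  for (nc in c(8, 16, 32)) {
    g2 <- build_radial_grid(geom, nc, nc)
    expect_identical(g2$r[g2$interface_index], 0.695)
    expect_equal(sum(g2$measure), sum(g$measure), tolerance = 1e-12)
  }
  expect_error(build_radial_grid(geom, 2, 8), "at least 4")
  expect_error(
    build_radial_grid(particle_geometry(shape = "ellipse",
                                        eccentricity = 0.3), 8, 8),
    "unsupported shape")
})

test_that("3D grid measures sum to spherical volumes", {
  g3 <- particle_geometry(dimension = "3D")
  g <- build_radial_grid(g3, 10, 10)
  expect_equal(sum(g$measure), 4 / 3 * pi * 0.76^3, tolerance = 1e-12)
  expect_equal(sum(g$measure_core), 4 / 3 * pi * 0.695^3, tolerance = 1e-12)
})
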