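test_that("meshes resolve both subdomains accurately", {
  geom <- ref_geom()
  mesh <- ref_mesh()
  expect_lt(abs(mesh$core_area - core_volume(geom)) / core_volume(geom),
            0.005)
  expect_lt(abs(mesh$shell_area - shell_volume(geom)) / shell_volume(geom),
            0.005)
  expect_gt(mesh$min_angle_deg, 10)
  # every core triangle has all vertices inside (or on) the core ellipse
  incore <- mesh$region == "core"
  rr <- sqrt(rowSums(mesh$nodes^2))
  for (v in 1:3) {
    expect_true(all(rr[mesh$triangles[incore, v]] <= 0.695 + 1e-9))
    expect_true(all(rr[mesh$triangles[!incore, v]] >= 0.695 - 1e-9))
  }
  # lumped measures partition the subdomain areas
  expect_equal(sum(mesh$lump_core), mesh$core_area, tolerance = 1e-12)
  expect_equal(sum(mesh$lump_shell), mesh$shell_area, tolerance = 1e-12)
  # positive orientation
  tri <- mesh$triangles; nd <- mesh$nodes
  a2 <- (nd[tri[, 2], 1] - nd[tri[, 1], 1]) *
        (nd[tri[, 3], 2] - nd[tri[, 1], 2]) -
        (nd[tri[, 3], 1] - nd[tri[, 1], 1]) *
        (nd[tri[, 2], 2] - nd[tri[, 1], 2])
  expect_true(all(a2 > 0))
})

test_that("mesh refinement reduces the geometric area error monotonically", {
  geom <- ref_geom()
  errs <- vapply(c(0.16, 0.08, 0.04), function(h) {
    m <- build_mesh(geom, h)
    abs(m$core_area - core_volume(geom)) / core_volume(geom)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("elliptical meshes keep quality and preserve areas", {
  geom <- ref_geom()
  for (lam in c(0.3, 0.6, 0.9)) {
    m <- build_mesh(make_ellipse(geom, lam), 0.16)
    expect_gt(m$min_angle_deg, 10)
    expect_lt(abs(m$core_area - core_volume(geom)) / core_volume(geom),
              0.005)
    expect_lt(abs(m$shell_area - shell_volume(geom)) / shell_volume(geom),
              0.005)
  }
  # the lambda = 0 ellipse is the disk
  m0 <- build_mesh(make_ellipse(geom, 0), 0.16)
  md <- ref_mesh()
  expect_equal(m0$core_area, md$core_area, tolerance = 1e-12)
  expect_equal(m0$nodes, md$nodes, tolerance = 1e-12)
  expect_error(build_mesh(geom, 1), "mesh resolution")
})

test_that("all-zero initial data stays identically zero", {
  sim <- simulate_particle_fem(ref_mesh(), ref_params(),
                               fast_opts(t_end = 10),
                               c_init = 0, b0_init = 0, b1_init = 0)
  expect_true(all(sim$release$Mrel_pct == 0))
  expect_true(all(abs(sim$final_state$c) < 1e-14))
})

test_that("FEM and radial solvers agree on the disk", {
  sr <- ref_sim()
  sf <- ref_sim_fem()
  expect_lt(max(abs(sr$release$Mrel_pct - sf$release$Mrel_pct)), 1)
  expect_lt(sf$diagnostics$mass_balance_residual, 1e-4)
  expect_true(all(diff(sf$release$Mrel_pct) >= -1e-10))
})

test_that("release depends continuously on the eccentricity", {
  opts <- fast_opts()
  s0 <- simulate_particle_fem(build_mesh(make_ellipse(ref_geom(), 0)),
                              ref_params(), opts)
  s1 <- simulate_particle_fem(build_mesh(make_ellipse(ref_geom(), 0.001)),
                              ref_params(), opts)
  expect_lt(max(abs(s0$release$Mrel_pct - s1$release$Mrel_pct)), 0.1)
})

test_that("FEM release curve is mesh independent", {
  coarse <- ref_sim_fem()
  fine <- simulate_particle_fem(build_mesh(ref_geom(), 0.08),
                                ref_params(), solver_options())
  expect_lt(abs(coarse$release$Mrel_pct[401] - fine$release$Mrel_pct[401]),
            0.2)
})

test_that("mesh CSV export round-trips the node and triangle tables", {
  mesh <- ref_mesh()
  pre <- file.path(tempdir(), "mesh_test")
  fn <- write_mesh_csv(mesh, pre)
  nodes <- read.csv(fn[1])
  tris <- read.csv(fn[2])
  expect_equal(nrow(nodes), nrow(mesh$nodes))
  expect_equal(nrow(tris), nrow(mesh$triangles))
  expect_equal(nodes$x_um, mesh$nodes[, 1], tolerance = 1e-12)
  expect_equal(sum(nodes$boundary), sum(mesh$boundary))
  unlink(fn)
})
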