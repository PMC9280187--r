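test_that("no dissolution means no release", {
  sim <- simulate_particle(ref_geom(), reference_parameters(beta = 0),
                           fast_opts())
  expect_true(all(sim$release$Mrel_pct == 0))
  expect_equal(sim$release$Mtot_ug[201], sim$release$Mtot_ug[1],
               tolerance = 1e-10)
})

test_that("semi-discrete decay of the first Bessel eigenmode matches D z1^2 / R^2", {
  # single uniform-D disk, no reactions, initial field J0(z1 r / R1):
  # Mtot(t) should decay as exp(-D z1^2 t / R^2)
  geom <- ref_geom()
  p <- reference_parameters(D1 = 2.5e-10, beta = 0, k = 0)  # D1 = D0
  grid <- build_radial_grid(geom, 40, 20)
  z1 <- 2.404825557695773
  prof <- besselJ(z1 * grid$r / geom$R1, 0)
  istar <- grid$interface_index
  init <- initial_state(grid, p, b0 = 0,
                        c0 = prof[1:istar],
                        c1 = prof[istar:length(grid$r)], b1 = 0)
  t_s <- c(0, 2, 4, 6)
  opts <- solver_options(n_core = 40, n_shell = 20, t_end = 6 / 3600,
                         output_times = t_s / 3600)
  sim <- simulate_particle(geom, p, opts, init = init)
  R_cm <- geom$R1 * 1e-4
  rate_exact <- p$D0 * z1^2 / R_cm^2
  m <- sim$release$Mtot_ug
  rates <- -diff(log(m)) / diff(t_s)
  expect_equal(rates, rep(rate_exact, 3), tolerance = 0.01)
})

test_that("linear-diffusion limit matches the Bessel series solution", {
  # fully dissolved initial drug, inert shell with core diffusivity:
  # the two-layer solver degenerates to diffusion in a homogeneous disk
  geom <- ref_geom()
  p <- reference_parameters(D1 = 2.5e-10, beta = 0, k = 0)
  grid <- build_radial_grid(geom, 40, 20)
  init <- initial_state(grid, p, b0 = 0, c0 = 1, c1 = 1, b1 = 0)
  t_s <- seq(0, 30, by = 0.5)
  opts <- solver_options(n_core = 40, n_shell = 20, t_end = 30 / 3600,
                         output_times = t_s / 3600)
  sim <- simulate_particle(geom, p, opts, init = init)
  exact <- 100 * analytic_disk_release(p$D0, geom$R1 * 1e-4, t_s)
  after <- t_s >= 1   # past the initial transient
  expect_lt(max(abs(sim$release$Mrel_pct[after] - exact[after])), 0.5)
})

test_that("analytic disk release is a proper cumulative fraction", {
  expect_identical(analytic_disk_release(1, 1, 0), 0)
  expect_equal(analytic_disk_release(1, 1, 10), 1, tolerance = 1e-10)
  v <- analytic_disk_release(1, 1, seq(0.01, 1, by = 0.01))
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_error(analytic_disk_release(1, 1, -1), "nonnegative")
  expect_error(analytic_disk_release(0, 1, 1), "positive")
})

test_that("reference simulation satisfies the conservation and shape invariants", {
  sim <- ref_sim()
  rel <- sim$release
  expect_identical(rel$Mrel_pct[1], 0)
  expect_true(all(diff(rel$Mrel_pct) >= -1e-10))
  expect_true(all(diff(rel$Mtot_ug) <= 1e-16))
  expect_lt(sim$diagnostics$mass_balance_residual, 1e-6)
  expect_true(all(rel$Mrel_pct <= 100))
  # everything not released is still inside: bound + remaining ~ 100 - released
  s <- release_summary(sim)
  expect_lt(s$bound_fraction_pct, 100 - s$released_pct_final + 1e-6)
})

test_that("solid phase decreases and bound phase grows monotonically in time", {
  opts <- solver_options(n_core = 24, n_shell = 12, t_end = 400,
                         snapshot_times = c(24, 96, 200, 400))
  sim <- simulate_particle(ref_geom(), ref_params(), opts)
  snaps <- sim$snapshots
  for (i in seq_len(length(snaps) - 1)) {
    expect_true(all(snaps[[i + 1]]$b0 <= snaps[[i]]$b0 + 1e-12))
    expect_true(all(snaps[[i + 1]]$b1 >= snaps[[i]]$b1 - 1e-12))
  }
  # dissolved concentration never exceeds the (internal) solubility
  sc <- coreshell:::.internal_scales(ref_params(), ref_geom())
  for (s in snaps) expect_true(all(c(s$c0, s$c1) <= sc$S))
})

test_that("a less permeable shell never accelerates release", {
  base <- simulate_particle(ref_geom(), ref_params(), fast_opts())
  slow <- simulate_particle(ref_geom(),
                            reference_parameters(D1 = 2.5e-12),
                            fast_opts())
  expect_true(all(slow$release$Mrel_pct <= base$release$Mrel_pct + 1e-9))
})

test_that("release curve is grid converged", {
  fine <- simulate_particle(ref_geom(), ref_params(),
                            solver_options(n_core = 80, n_shell = 40))
  coarse <- ref_sim()
  expect_lt(abs(fine$release$Mrel_pct[401] - coarse$release$Mrel_pct[401]),
            0.1)
})

test_that("simulation is deterministic", {
  a <- simulate_particle(ref_geom(), ref_params(), fast_opts(t_end = 50))
  b <- simulate_particle(ref_geom(), ref_params(), fast_opts(t_end = 50))
  expect_identical(a$release, b$release)
})

test_that("3D spherical mode runs and conserves mass", {
  g3 <- particle_geometry(dimension = "3D")
  sim <- simulate_particle(g3, ref_params(), fast_opts(t_end = 100))
  expect_lt(sim$diagnostics$mass_balance_residual, 1e-6)
  expect_true(all(diff(sim$release$Mrel_pct) >= -1e-10))
  expect_equal(sim$release$Mtot_ug[1], 2.5e-4, tolerance = 1e-10)
})
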