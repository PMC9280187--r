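# Shared fixtures: reference geometry/parameters and memoized expensive
# simulations so that several test files can reuse one run.

ref_geom <- function() particle_geometry()
ref_params <- function(...) reference_parameters(...)

# coarse-but-adequate options for fast tests
fast_opts <- function(t_end = 400, ...)
  solver_options(n_core = 24, n_shell = 12, t_end = t_end,
                 output_times = seq(0, t_end, length.out = 201L), ...)

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# reference-case radial simulation at production resolution, 400 h
ref_sim <- function()
  memo("ref_sim", simulate_particle(ref_geom(), ref_params(),
                                    solver_options()))

# reference-case FEM simulation on the h = 0.16 um disk mesh
ref_sim_fem <- function()
  memo("ref_sim_fem", simulate_particle_fem(ref_mesh(), ref_params(),
                                            solver_options()))

ref_mesh <- function() memo("ref_mesh", build_mesh(ref_geom(), 0.16))
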