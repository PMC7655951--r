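# shared fixtures: default parameters and a coarse mesh spec that keeps the
# unit-test solves fast (acceptance tests use the default resolution)
params_default <- default_parameters()

coarse_spec <- function(...) {
  mesh_spec(n_theta = 24, membrane_layers = 2, n_extracellular = 10,
            n_cytoplasm = 6, n_nucleoplasm = 5, outer_radius = 35e-6, ...)
}

# quick solver options for short linear runs
quick_opts <- function(...) {
  solver_options(dt = 0.05e-9, max_sweeps = 2L, ...)
}
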