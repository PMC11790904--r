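# shared fixtures: coarse-sampled SICM settings keep noise-free unit tests
# fast; the instrument-realistic fine default is exercised in the acceptance
# suite only.

test_pipette <- function(...) pipette_params(...)

coarse_curve <- function(E, pipette = test_pipette(), ...) {
  synth_approach_curve(E, pipette, dz_fine_nm = 1, n_plateau = 50, ...)
}

coarse_scan <- function(phantom, pipette = test_pipette(), ...) {
  simulate_scan(phantom, pipette, dz_fine_nm = 1, n_plateau = 50, ...)
}

small_phantom <- function(...) {
  make_phantom(nx = 16, ny = 16, extent_um = 10, process_length_um = 4, ...)
}

small_cohort <- function(n = 5, seed = 1, ...) {
  simulate_cohort(cohort_params(n_cells = n, seed = seed, ...))
}
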