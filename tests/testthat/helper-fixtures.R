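# Small in-code fixtures shared across test files.

# A coarse grid keeps pretreatment/PLS tests fast while preserving the
# band structure of the default library.
coarse_grid <- function() make_grid(1100, 2500, 2)

# Deterministic random spectra set: smooth curves + noise.
random_set <- function(n = 6, grid = make_grid(400, 500, 5), seed = 42) {
  set.seed(seed)
  p <- length(grid)
  vals <- t(replicate(n, {
    base <- 0.5 + 0.2 * sin(seq(0, pi, length.out = p) + runif(1, 0, pi))
    base * (1 + rnorm(1, 0, 0.1)) + rnorm(1, 0, 0.05) + rnorm(p, 0, 0.01)
  }))
  spectra_set(vals, grid, sample_id = sprintf("S%02d", seq_len(n)))
}

# Single-breed design with controllable SDs, for degenerate-noise tests.
one_breed_design <- function(sd_scale = 1, eggs = 10, pool = 2, seed = 1) {
  prof <- default_profiles()[["PA-C"]]
  prof$traits$sd <- prof$traits$sd * sd_scale
  study_design(breeds = list(prof), eggs_per_breed = eggs, pool_size = pool,
               seed = seed)
}

# A tiny yolk-style dataset (composition + fresh/freeze-dried spectra) on
# the coarse grid, used by the calibration and acceptance tests.
yolk_dataset <- function(seed = 1, eggs = 50) {
  comp <- generate_composition(study_design(eggs_per_breed = eggs, seed = seed),
                               part = "yolk")
  lib <- default_component_library(coarse_grid())
  list(comp = comp,
       fresh = generate_spectra(comp, lib, "fresh", seed = seed),
       fd = generate_spectra(comp, lib, "freeze-dried", seed = seed),
       lib = lib)
}
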