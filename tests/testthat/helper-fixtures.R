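# Small scene specifications reused across test files.

tiny_spec <- function(...) {
  scene_spec(n_seeds_per_class = c(3, 3), rng_seed = 11, ...)
}

# noiseless deterministic scene: planted reflectance recoverable exactly
clean_spec <- function(...) {
  scene_spec(
    n_seeds_per_class = c(3, 3), noise_sd = 0, scatter_sd = 0,
    class_offset = 1, rng_seed = 11, ...
  )
}

# small labelled dataset for classifier tests
small_dataset <- function(n_per_class = 40, seed = 5, ...) {
  generate_spectral_dataset(
    scene_spec(n_seeds_per_class = c(n_per_class, n_per_class),
               rng_seed = seed, ...),
    n_per_class
  )
}

# reduced SVM grids keep unit tests quick; coverage of the full default
# grid is exercised in the acceptance pipeline
small_c_grid <- 2^seq(-2, 10, 2)
small_g_grid <- 2^seq(-6, 6, 2)
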