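# Shared fixtures are generated programmatically; nothing is stored on
# disk. Small worlds keep the default suite fast, the acceptance file
# uses its own scale.

tiny_sim <- function(..., seed = 42L) {
  sim_config(n_neurons = 12L, T = 30L, prep_bins = 10L,
             trials_per_epoch = c(BL = 2L, AD = 2L, WO = 2L),
             seed = seed, ...)
}

tiny_dataset <- function(..., seed = 42L) {
  generate_dataset(tiny_sim(..., seed = seed))$dataset
}

tiny_model_cfg <- function(...) {
  defaults <- list(n_factors = 3L, n_control = 2L, generator_dim = 8L,
                   encoder_dim = 6L, prep_bins = 10L, behavior_dims = 2L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# a cache shared across test files within one run (training is costly)
.band_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .band_test_cache)) {
    assign(key, builder(), envir = .band_test_cache)
  }
  get(key, envir = .band_test_cache)
}
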