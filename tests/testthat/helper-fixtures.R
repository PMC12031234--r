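# Shared fixtures. Everything is generated in code; the expensive standard
# 128x128 pipeline runs are computed once per session and memoized so the
# four quality-gate criteria and the ablation share them.

tiny_phantom <- function(grid = 32, n_slices = 1, sigma = 0.05, fluor = 0.1,
                         seed = 1) {
  generate_spheroid_phantom(phantom_spec(
    grid_size = grid, n_slices = n_slices, spheroid_diameter = 0.6 * 635,
    noise_sigma = sigma, fluor_amplitude = fluor, seed = seed))
}

random_slice <- function(n = 8, seed = 1) {
  set.seed(seed)
  image_slice(matrix(runif(n * n), n, n))
}

fast_dip <- function(seed = 1, iters = 150) {
  dip_config(iterations_max = iters, seed = seed)
}

.run_cache <- new.env(parent = emptyenv())

standard_run <- function() {
  if (is.null(.run_cache$full))
    .run_cache$full <- run_pipeline(pipeline_config())
  .run_cache$full
}

ablation_run <- function() {
  if (is.null(.run_cache$ablation))
    .run_cache$ablation <- run_pipeline(pipeline_config(
      preprocess_enabled = FALSE, postprocess_enabled = FALSE))
  .run_cache$ablation
}
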