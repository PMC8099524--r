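# Shared fixtures. The small trained model is expensive (~1 min), so it is
# built once per test run and cached for every file that needs it.

.fixture_cache <- new.env(parent = emptyenv())

noise_free_config <- function(image_size = 32, n_samples = 6, seed = 33,
                              ...) {
  phantom_config(image_size = image_size, n_samples = n_samples,
                 noise_sd = 0, texture_scale = 0, seed = seed, ...)
}

# a compact trained model on noise-free 32x32 phantoms, shared across tests
small_trained <- function() {
  if (is.null(.fixture_cache$st)) {
    ph <- generate_phantoms(noise_free_config())
    .fixture_cache$ph <- ph
    .fixture_cache$st <- train(ph, train_config(image_size = 32, seed = 5,
                                                max_steps = 150))
    .fixture_cache$held_out <- generate_phantoms(noise_free_config(seed = 44,
                                                                   n_samples = 4))
  }
  .fixture_cache
}

random_mask <- function(n = 16, p = 0.3) {
  m <- matrix(rbinom(n * n, 1, p), n, n)
  if (sum(m) == 0) m[sample(n * n, 1)] <- 1
  m
}
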