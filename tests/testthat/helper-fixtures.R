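# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Full-size SDEM at the default build parameters; several tests and the
# acceptance suite share it to avoid rebuilding (~20 s).
shared_sdem <- function() {
  if (is.null(.fixtures$sdem)) {
    .fixtures$sdem <- build_sdem(n_max = 200, sigma_max = 100, B = 50, seed = 42)
  }
  .fixtures$sdem
}

# Default bivalent synthetic dataset (shared where the seed does not matter).
shared_dataset <- function() {
  if (is.null(.fixtures$dataset)) {
    .fixtures$dataset <- simulate_dataset(sim_config(seed = 7))
  }
  .fixtures$dataset
}

# A compact pipeline config used by the smoke/determinism tests.
small_run_config <- function(seed = 1, ...) {
  run_config(
    sim = sim_config(n_promoters = 400, n_sequence_features = 2, seed = seed),
    sdem_n_max = 150, sdem_sigma_max = 100, sdem_B = 20,
    ks = c(1, 2), include_full = FALSE, seed = seed, ...
  )
}
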