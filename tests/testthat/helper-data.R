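# Shared small builders used across test files.

small_manifest <- function(n_setups = 8, n_replicates = 2,
                           ec_levels = c(1, 5, 10)) {
  panel <- default_panel()
  setups <- enumerate_setups(panel)
  keep <- unique(c(1:4, seq(5, nrow(setups), length.out = n_setups - 4)))
  expand_manifest(setups[sort(round(keep)), ], panel,
                  ec_levels = ec_levels, n_replicates = n_replicates)
}

small_dataset <- function(..., params = sim_params(), seed = 11L) {
  man <- small_manifest(...)
  sim <- simulate_dataset(man, params, seed = seed)
  feats <- featurize_dataset(sim$traces, injection_time = sim$injection_time)
  list(manifest = man, sim = sim, features = feats, truth = sim$truth)
}
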