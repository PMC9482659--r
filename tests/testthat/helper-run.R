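# One full-size pipeline run (60x60 grid, 12 countries, 30 virtual species,
# 5-algorithm ensemble, both scenario families x 3 horizons) shared by the
# recovery and scenario-ordering acceptance tests. Memoized so the suite
# pays its cost once.
.run_cache <- new.env(parent = emptyenv())

full_run <- function() {
  if (is.null(.run_cache$run))
    .run_cache$run <- run_pipeline(default_config(seed = 1), quiet = TRUE)
  .run_cache$run
}
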