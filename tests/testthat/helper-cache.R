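# One full default-design study per seed, computed lazily and shared by the
# tests that assert different properties of the same run.
.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed = 7) {
  key <- paste0("run", seed)
  if (is.null(.study_cache[[key]])) {
    ds <- simulate_dataset(simulation_design(seed = seed))
    dir <- file.path(tempdir(), paste0("herimap_accept_", seed))
    res <- run_pipeline(ds$genotypes, ds$volumes, ds$covariates,
                        config = pipeline_config(seed = seed), out_dir = dir)
    .study_cache[[key]] <- list(ds = ds, res = res, dir = dir)
  }
  .study_cache[[key]]
}
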