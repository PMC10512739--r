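# Reduced-scale planted-signal benchmark runs, shared by the recovery
# and stability acceptance checks. Computed once per test session.

.benchmark_cache <- new.env(parent = emptyenv())

# For each seed: generate the reduced benchmark, pick the penalty from
# the default three-point grid for the group method and the
# single-subject baseline on identical sampling plans, and return both
# winning runs plus the planted cluster ids.
benchmark_runs <- function(seeds = 1:5) {
  key <- paste0("runs_", paste(seeds, collapse = "_"))
  if (!is.null(.benchmark_cache[[key]])) return(.benchmark_cache[[key]])
  out <- lapply(seeds, function(s) {
    ds <- generate_dataset(synthetic_spec("reduced", seed = s))
    cfg <- benchmark_config(seed = s)
    grp <- select_lambda(ds$subjects, ds$mask, ds$parcellation_truth, cfg,
                         method = "group")
    sgl <- select_lambda(ds$subjects, ds$mask, ds$parcellation_truth, cfg,
                         method = "single")
    list(seed = s, truth = ds$truth$discriminative_regions,
         n_sel = cfg$n_sel, group = grp, single = sgl)
  })
  .benchmark_cache[[key]] <- out
  out
}
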