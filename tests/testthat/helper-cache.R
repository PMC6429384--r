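# The seven-species pipeline is the most expensive object in the suite;
# several files assert different properties of the same runs, so fixture
# truths and pipeline results are computed once per seed and shared.

.satfam_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed) {
  key <- paste0("fx", seed)
  if (is.null(.satfam_cache[[key]])) {
    .satfam_cache[[key]] <- fixture("seven_species", seed = seed)
  }
  .satfam_cache[[key]]
}

cached_pipeline <- function(seed) {
  key <- paste0("pl", seed)
  if (is.null(.satfam_cache[[key]])) {
    fx <- cached_fixture(seed)
    outdir <- file.path(tempdir(), paste0("satfam_seed", seed))
    .satfam_cache[[key]] <- list(fx = fx,
                                 res = run_pipeline(fx$truth, outdir = outdir),
                                 outdir = outdir)
  }
  .satfam_cache[[key]]
}
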