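# One full-scale default study + pipeline run, shared (memoised) across the
# acceptance tests so the expensive NB-GLMM stage runs once per suite.

.study_cache <- new.env(parent = emptyenv())

default_study_run <- function() {
  if (is.null(.study_cache$run)) {
    study <- simulate_study(sim_params(), seed = 1902)
    res <- suppressWarnings(
      run_three_viewpoints(study$counts, study$metadata, verbose = FALSE))
    .study_cache$run <- list(study = study, res = res)
  }
  .study_cache$run
}

# designated stable class per normalization mode
mode_stable_class <- c(per_library_size = "library_stable",
                       per_total_rna = "totalrna_stable",
                       per_sample_size = "tissue_stable")
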