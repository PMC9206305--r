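#' Run the full three-viewpoint analysis
#'
#' Orchestrates the whole pipeline on a count matrix and metadata:
#' \enumerate{
#'   \item robust expression filter (min count `min_count_stable` everywhere);
#'   \item per mode: denominators (TMM-scaled library size / constant /
#'     tissue mass), log-CPM, LMM stability screen (max |t| <
#'     `t_threshold`) and ICC ranking, top-`top_k` stable set;
#'   \item stable-gene sample references on the common count scale;
#'   \item reference-ratio analysis for every ordered mode pair;
#'   \item DE universe (min count `min_count_de`, stable genes excluded),
#'     NB-GLMM DE per mode with log-reference offsets, BH-FDR per contrast;
#'   \item cross-mode membership, intersections and conflicts.
#' }
#'
#' @param counts gene x sample count matrix.
#' @param meta per-sample metadata (see [read_metadata()]).
#' @param config a [norm_config()] list.
#' @param verbose emit progress messages to standard error (default TRUE).
#' @return object of class `three_viewpoints`: `filtered_genes`,
#'   `denominators`, `stable_reports`, `stable_sets`, `references`,
#'   `reference_ratios`, `de_universe`, `de_results`, `comparison`, `summary`,
#'   `config`.
#' @export
run_three_viewpoints <- function(counts, meta, config = norm_config(),
                                 verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  al <- validate_design(counts, meta)
  counts <- al$counts; meta <- al$meta

  filtered <- robust_filter(counts, config$min_count_stable)
  say(sprintf("robust filter: %d / %d genes with count >= %g in every sample",
              length(filtered), nrow(counts), config$min_count_stable))
  if (!length(filtered)) stop("no genes pass the robust expression filter")

  tmm <- tmm_factors(counts, trim_m = config$trim_m, trim_a = config$trim_a)
  denoms <- list(
    per_library_size = denominators(counts, meta, "per_library_size", factors = tmm),
    per_total_rna = denominators(counts, meta, "per_total_rna",
                                 depth_rescale = config$totalrna_depth_rescale),
    per_sample_size = denominators(counts, meta, "per_sample_size")
  )

  stable_reports <- list()
  for (mode in names(denoms)) {
    lc <- log_cpm(cpm(counts[filtered, , drop = FALSE], denoms[[mode]]))
    stable_reports[[mode]] <- screen_and_rank(
      lc, meta, t_threshold = config$t_threshold, top_k = config$top_k,
      include_volume = config$screen_include_volume,
      include_interactions = config$screen_include_interactions)
    say(sprintf("%s: %d survivors of the |t| < %g screen; top-%d stable set selected",
                mode, sum(stable_reports[[mode]]$screened$passed_screen),
                config$t_threshold, config$top_k))
  }
  stable_sets <- lapply(stable_reports, `[[`, "top_k")

  # references on the common count scale: a mode's stable genes estimate that
  # mode's effective per-sample denominator
  references <- list()
  for (mode in names(stable_sets)) {
    cm <- counts
    attr(cm, "mode_label") <- mode
    references[[mode]] <- sample_reference(cm, stable_sets[[mode]])
  }

  pairs <- expand.grid(num = names(references), den = names(references),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$num != pairs$den, ]
  reference_ratios <- list()
  for (i in seq_len(nrow(pairs))) {
    nm <- paste(pairs$num[i], "over", pairs$den[i], sep = "_")
    reference_ratios[[nm]] <- reference_ratio(references[[pairs$num[i]]],
                                              references[[pairs$den[i]]], meta)
  }

  universe <- de_gene_set(counts, config$min_count_de,
                          exclude = unique(unlist(stable_sets)))
  say(sprintf("DE universe: %d genes (min count %g, %d stable genes excluded)",
              length(universe), config$min_count_de,
              length(unique(unlist(stable_sets)))))

  de_results <- list()
  for (mode in names(references)) {
    say("fitting NB GLMMs for mode ", mode, " ...")
    de_results[[mode]] <- run_mode_de(counts, meta, references[[mode]],
                                      genes = universe, alpha = config$fdr_alpha,
                                      nagq = config$nagq)
  }
  # keep the modes' universes identical: a gene failing in any mode is ns in all
  failed <- unique(unlist(lapply(de_results, function(r) r$gene_id[!r$converged])))
  if (length(failed)) {
    say(length(failed), " gene(s) failed to fit in >= 1 mode; set to ns in all modes")
    for (mode in names(de_results)) {
      idx <- de_results[[mode]]$gene_id %in% failed
      de_results[[mode]]$direction[idx] <- "ns"
    }
  }

  comparison <- compare_modes(de_results)
  structure(list(
    filtered_genes = filtered,
    tmm_factors = tmm,
    denominators = denoms,
    stable_reports = stable_reports,
    stable_sets = stable_sets,
    references = references,
    reference_ratios = reference_ratios,
    de_universe = universe,
    de_results = de_results,
    comparison = comparison,
    summary = summarize_comparison(comparison),
    config = config
  ), class = "three_viewpoints")
}

#' @export
print.three_viewpoints <- function(x, ...) {
  cat("Three-viewpoint transcriptome analysis\n")
  cat(sprintf("  stable candidates: %d genes; DE universe: %d genes\n",
              length(x$filtered_genes), length(x$de_universe)))
  for (mode in names(x$stable_sets))
    cat(sprintf("  %s stable set: %s\n", mode,
                paste(x$stable_sets[[mode]], collapse = ", ")))
  cat("  intersection summary (per contrast/direction):\n")
  print(utils::head(x$summary, 12))
  invisible(x)
}
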