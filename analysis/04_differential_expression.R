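#!/usr/bin/env Rscript
# Step 4: per-gene differential expression under each viewpoint.
#
# Fits the NB GLMM (participant random intercept, time fixed effects, log
# sample reference as offset) for every gene of the shared DE universe under
# each of the three modes, with BH-FDR per time contrast. This is the slow
# step (~a few thousand model fits). Writes per-mode result tables under
# results/de/.

suppressMessages(library(trinorm))

counts <- read_counts("results/data/counts.tsv")
meta <- read_metadata("results/data/metadata.csv")
al <- validate_design(counts, meta)
cfg <- norm_config()
out_dir <- "results/de"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

refs <- lapply(NORMALIZATION_MODES, function(mode) {
  r <- utils::read.delim(file.path("results/stable_genes",
                                   paste0("sample_reference_", mode, ".tsv")))
  structure(r, mode = mode, class = c("sample_reference", "data.frame"))
})
names(refs) <- NORMALIZATION_MODES

stable_union <- unique(unlist(lapply(NORMALIZATION_MODES, function(mode)
  utils::read.delim(file.path("results/stable_genes",
                              paste0("top10_", mode, ".tsv")))$gene_id)))
universe <- de_gene_set(al$counts, cfg$min_count_de, exclude = stable_union)
message("DE universe: ", length(universe), " genes (stable genes excluded)")

for (mode in NORMALIZATION_MODES) {
  message("fitting ", mode, " ...")
  de <- run_mode_de(al$counts, al$meta, refs[[mode]], genes = universe,
                    alpha = cfg$fdr_alpha, nagq = cfg$nagq)
  utils::write.table(de, file.path(out_dir, paste0("de_", mode, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ct in unique(de$contrast))
    message(sprintf("  %s: %d up, %d down of %d", ct,
                    sum(de$direction == "up" & de$contrast == ct),
                    sum(de$direction == "down" & de$contrast == ct),
                    length(universe)))
}
message("wrote per-mode DE tables to ", out_dir)
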