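#!/usr/bin/env Rscript
# Step 1: generate the synthetic resistance-training study.
#
# Emulates the study dimensions (25 participants x 2 legs x weeks 0/2/12,
# fixed 1000 ng total-RNA input) with a global total-RNA amplification of
# +27% / +17% per mg tissue and a larger mRNA-pool amplification, plus
# designated stable gene classes for each normalization viewpoint.
# Writes counts (TSV), metadata (CSV), truth tables and parameters (JSON)
# under results/data/.

suppressMessages({ library(trinorm); library(jsonlite) })

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- sim_params()
study <- simulate_study(params, seed = seed)
print(study)

write_counts(study$counts, file.path(out_dir, "counts.tsv"))
utils::write.csv(study$metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
truth_genes <- data.frame(
  gene_id = names(study$truth$gene_class),
  gene_class = unname(study$truth$gene_class),
  per_mg_log_fc_week2 = study$truth$per_mg_log_fc[, "week2"],
  per_mg_log_fc_week12 = study$truth$per_mg_log_fc[, "week12"],
  dispersion = unname(study$truth$dispersion),
  participant_sd = unname(study$truth$participant_sd))
utils::write.table(truth_genes, file.path(out_dir, "truth_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(study$truth$sample_denominator_truth,
                   file.path(out_dir, "truth_samples.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_json(params[setdiff(names(params), NULL)], file.path(out_dir, "params.json"),
           auto_unbox = TRUE, digits = NA)
message("wrote study (", nrow(study$counts), " genes x ", ncol(study$counts),
        " samples) to ", out_dir)
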