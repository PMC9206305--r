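#!/usr/bin/env Rscript
# Step 2: per-sample denominators for the three normalization viewpoints.
#
# Computes TMM scaling factors and the three denominator sets (TMM-scaled
# library size / constant total-RNA / tissue mass) and writes them, plus the
# log-CPM matrix of robustly expressed genes per mode, under results/normalize/.

suppressMessages(library(trinorm))

counts <- read_counts("results/data/counts.tsv")
meta <- read_metadata("results/data/metadata.csv")
al <- validate_design(counts, meta)
cfg <- norm_config()
out_dir <- "results/normalize"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tmm <- tmm_factors(al$counts, trim_m = cfg$trim_m, trim_a = cfg$trim_a)
message(sprintf("TMM factors: range %.3f - %.3f (geometric mean 1)",
                min(tmm), max(tmm)))

keep <- robust_filter(al$counts, cfg$min_count_stable)
message(length(keep), " genes pass the robust filter (count >= ",
        cfg$min_count_stable, " in every sample)")

for (mode in NORMALIZATION_MODES) {
  d <- switch(mode,
    per_library_size = denominators(al$counts, al$meta, mode, factors = tmm),
    denominators(al$counts, al$meta, mode))
  utils::write.table(d, file.path(out_dir, paste0("denominators_", mode, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lc <- log_cpm(cpm(al$counts[keep, , drop = FALSE], d))
  write_counts(round(unclass(lc), 6), file.path(out_dir, paste0("logcpm_", mode, ".tsv")))
}
message("wrote denominator sets and log-CPM matrices to ", out_dir)
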