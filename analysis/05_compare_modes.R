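#!/usr/bin/env Rscript
# Step 5: cross-mode comparison of DE calls (the overlap panel).
#
# Joins the three modes' direction calls, tabulates intersection patterns as
# proportions of all genes differentially expressed in any mode, and lists
# direction conflicts. Writes membership and summary tables plus plot-ready
# JSON under results/compare/.

suppressMessages({ library(trinorm); library(jsonlite) })

out_dir <- "results/compare"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

res <- lapply(NORMALIZATION_MODES, function(mode) {
  d <- utils::read.delim(file.path("results/de", paste0("de_", mode, ".tsv")))
  structure(d, mode = mode, class = c("de_result", "data.frame"))
})
names(res) <- NORMALIZATION_MODES

cmp <- compare_modes(res)
print(cmp)
summ <- summarize_comparison(cmp)

utils::write.table(cmp$membership, file.path(out_dir, "membership.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(summ, file.path(out_dir, "intersection_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cmp$conflicts, file.path(out_dir, "conflicts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_json(list(modes = cmp$modes, intersections = summ,
                n_conflicts = nrow(cmp$conflicts)),
           file.path(out_dir, "upset_data.json"), auto_unbox = TRUE, digits = NA)

conf2 <- cmp$conflicts[cmp$conflicts$contrast == "timeweek2" &
                         cmp$conflicts$dir_per_sample_size == "up" &
                         cmp$conflicts$dir_per_library_size == "down", ]
message(nrow(conf2),
        " genes up per-sample-size but down per-library-size at week 2")
message("wrote comparison tables to ", out_dir)
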