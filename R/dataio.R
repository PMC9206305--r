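#' Read a transcript count matrix from TSV
#'
#' Expects a tab-separated file with gene identifiers in the first column and
#' sample identifiers in the header. Values must be non-negative integers;
#' violations are reported with their row/column location.
#'
#' @param path path to a TSV file.
#' @return integer matrix (genes x samples) with gene and sample dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a gene-id column plus >= 1 sample column")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) , arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (first at gene %s, sample %s)",
                                  gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]) else ""
    stop("non-numeric count value", loc)
  }
  bad <- which(m < 0 | m != round(m) | is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("counts must be non-negative integers; offending value %s at gene %s, sample %s",
                 format(m[bad[1, , drop = FALSE]]), gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write a count (or numeric gene x sample) matrix to TSV
#'
#' @param x matrix with gene row names and sample column names.
#' @param path output path.
#' @param id_column name for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from CSV
#'
#' Requires columns `sample_id`, `participant`, `time`, `condition` and
#' `tissue_mass_mg` (`rna_input_ng` is optional). The `time` column is turned
#' into a factor whose baseline is `baseline_time` regardless of row order, so
#' downstream dummy coding always contrasts against baseline.
#'
#' @param path path to a CSV file.
#' @param baseline_time baseline time label (default `"week0"`); must occur in
#'   the data. Remaining levels keep their order of first appearance unless
#'   they match the canonical `week<k>` pattern, in which case they are ordered
#'   numerically.
#' @return data.frame of per-sample metadata.
#' @export
read_metadata <- function(path, baseline_time = "week0") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "participant", "time", "condition", "tissue_mass_mg")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  labs <- unique(as.character(df$time))
  if (!baseline_time %in% labs)
    stop("baseline time label '", baseline_time, "' not present in metadata; found: ",
         paste(labs, collapse = ", "))
  others <- setdiff(labs, baseline_time)
  wk <- suppressWarnings(as.numeric(sub("^week", "", others)))
  if (!anyNA(wk)) others <- others[order(wk)]
  df$time <- factor(df$time, levels = c(baseline_time, others))
  if (any(df$tissue_mass_mg <= 0 | is.na(df$tissue_mass_mg)))
    stop("tissue_mass_mg must be positive for every sample")
  df
}

#' Align a count matrix and its metadata
#'
#' Asserts one metadata row per count column and reorders metadata to the
#' count-column order, so downstream results are invariant to the column
#' permutation of the input files. Participants with incomplete time series
#' trigger a warning (not an error: legs are replicates and partially missing
#' series still contribute).
#'
#' @param counts gene x sample count matrix.
#' @param meta metadata data.frame (see [read_metadata()]).
#' @return list with elements `counts` and `meta`, aligned column-to-row.
#' @export
validate_design <- function(counts, meta) {
  if (is.null(colnames(counts))) stop("count matrix has no sample identifiers")
  absent <- setdiff(colnames(counts), meta$sample_id)
  if (length(absent))
    stop("sample(s) in counts absent from metadata: ", paste(absent, collapse = ", "))
  unused <- setdiff(meta$sample_id, colnames(counts))
  if (length(unused))
    warning("metadata row(s) without count column are dropped: ",
            paste(unused, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  n_per <- table(meta$participant)
  if (any(n_per < 2))
    stop("participant(s) with < 2 samples: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  incomplete <- names(n_per)[n_per < max(n_per)]
  if (length(incomplete))
    warning("participant(s) with incomplete series: ",
            paste(incomplete, collapse = ", "))
  list(counts = counts, meta = meta)
}

#' Analysis configuration defaults
#'
#' Thresholds and options of the three-viewpoint pipeline: the robust
#' expression filter for stable-gene candidates (min count 30 in every
#' sample), the |t| < 1.5 stability screen, the top-10 stable set, the DE
#' universe filter (min count 1), the 5% FDR level, TMM trim fractions, and
#' model options.
#'
#' @param ... named overrides (unknown names error).
#' @return named list of configuration values.
#' @export
norm_config <- function(...) {
  cfg <- list(
    min_count_stable = 30,
    t_threshold = 1.5,
    top_k = 10,
    min_count_de = 1,
    fdr_alpha = 0.05,
    trim_m = 0.30,
    trim_a = 0.05,
    nagq = 5,
    screen_include_volume = TRUE,
    screen_include_interactions = TRUE,
    totalrna_depth_rescale = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown configuration option(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}
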