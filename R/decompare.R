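#' Differential expression gene universe
#'
#' Genes with count >= `min_count` in every sample, minus the excluded set
#' (the union of the three modes' stable reference genes). The universe is
#' fixed before testing and shared by all modes so that cross-mode comparisons
#' are over identical genes.
#'
#' @param counts gene x sample count matrix.
#' @param min_count minimum count per sample (default 1).
#' @param exclude gene identifiers to drop regardless of counts.
#' @return character vector of gene identifiers.
#' @export
de_gene_set <- function(counts, min_count = 1, exclude = character()) {
  keep <- rownames(counts)[apply(counts >= min_count, 1, all)]
  setdiff(keep, exclude)
}

#' Differential expression under one normalization mode
#'
#' Fits the NB GLMM ([fit_nb_glmm()]) per gene with the mode's log sample
#' reference as offset and time fixed effects (legs pooled as replicates),
#' collects per-contrast Wald statistics, applies Benjamini-Hochberg FDR
#' separately per time contrast across genes, and labels directions at level
#' `alpha`. Failed fits are retained as `ns` with `converged = FALSE`, never
#' silently dropped.
#'
#' @param counts gene x sample count matrix.
#' @param meta aligned metadata (factor `time`, baseline first).
#' @param reference a [sample_reference()] for the mode.
#' @param genes gene universe to test (default all rows of `counts`; see
#'   [de_gene_set()]).
#' @param alpha FDR level for direction calls (default 0.05).
#' @param nagq quadrature nodes for the per-gene fits.
#' @param include_volume add a volume fixed effect (default FALSE: legs are
#'   biological replicates).
#' @return data.frame of class `de_result`: gene_id, contrast, log_fc, se, z,
#'   p, adj_p, direction (`up` / `down` / `ns`), converged; attribute `mode`.
#' @export
run_mode_de <- function(counts, meta, reference, genes = rownames(counts),
                        alpha = 0.05, nagq = 5, include_volume = FALSE) {
  if (!all(genes %in% rownames(counts)))
    stop("gene universe contains identifiers absent from counts")
  ref <- reference$reference[match(colnames(counts), reference$sample_id)]
  if (anyNA(ref)) stop("reference does not cover all count samples")
  if (any(ref <= 0)) stop("sample references must be positive")
  off <- log(ref)
  time <- droplevels(meta$time)
  df <- data.frame(time = time, condition = factor(meta$condition))
  form <- if (include_volume && nlevels(df$condition) >= 2) ~ time + condition else ~ time
  X <- stats::model.matrix(form, df)
  contrasts <- paste0("time", levels(time)[-1])

  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    fit <- tryCatch(fit_nb_glmm(counts[genes[i], ], X, meta$participant,
                                offset = off, nagq = nagq),
                    error = function(e) NULL)
    ok <- !is.null(fit) && isTRUE(fit$converged)
    if (ok) {
      wt <- wald_table(fit, contrasts)
      res[[i]] <- data.frame(gene_id = genes[i], contrast = wt$term,
                             log_fc = wt$estimate, se = wt$se, z = wt$z, p = wt$p,
                             converged = TRUE, stringsAsFactors = FALSE)
    } else {
      res[[i]] <- data.frame(gene_id = genes[i], contrast = contrasts,
                             log_fc = NA_real_, se = NA_real_, z = NA_real_,
                             p = NA_real_, converged = FALSE,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$adj_p <- NA_real_
  for (ct in contrasts) {
    idx <- out$contrast == ct
    out$adj_p[idx] <- bh_adjust(out$p[idx])
  }
  out$direction <- "ns"
  sig <- !is.na(out$adj_p) & out$adj_p < alpha
  out$direction[sig & out$log_fc > 0] <- "up"
  out$direction[sig & out$log_fc < 0] <- "down"
  structure(out, mode = attr(reference, "mode"), alpha = alpha,
            class = c("de_result", "data.frame"))
}

#' Cross-mode comparison of differential expression calls
#'
#' Joins the per-mode direction calls into per-gene, per-contrast membership
#' triples, tabulates every non-empty direction pattern over the universe of
#' genes differentially expressed in at least one mode, and lists direction
#' conflicts (up in one mode, down in another).
#'
#' @param results named list of three [run_mode_de()] results (names are the
#'   modes; same gene universe and contrasts required).
#' @return object of class `mode_comparison`: `membership` (gene x contrast
#'   with one direction column per mode), `intersection_counts` (per contrast
#'   and pattern: count and proportion of DE-in-any-mode genes), `conflicts`.
#' @export
compare_modes <- function(results) {
  if (length(results) < 2) stop("need >= 2 mode results to compare")
  modes <- names(results)
  if (is.null(modes) || any(modes == ""))
    modes <- vapply(results, function(r) attr(r, "mode"), character(1))
  base <- results[[1]][, c("gene_id", "contrast")]
  key <- function(r) paste(r$gene_id, r$contrast)
  for (r in results[-1]) {
    if (!setequal(key(r), key(results[[1]])))
      stop("mode results cover different gene/contrast universes")
  }
  membership <- base
  for (j in seq_along(results)) {
    r <- results[[j]]
    membership[[paste0("dir_", modes[j])]] <-
      r$direction[match(key(base), key(r))]
  }
  dir_cols <- paste0("dir_", modes)
  any_de <- rowSums(membership[dir_cols] != "ns") > 0
  uni <- membership[any_de, , drop = FALSE]

  counts_list <- list()
  for (ct in unique(membership$contrast)) {
    sub <- uni[uni$contrast == ct, , drop = FALSE]
    denom <- nrow(sub)
    if (!denom) next
    pattern <- do.call(paste, c(sub[dir_cols], sep = "/"))
    tab <- table(pattern)
    counts_list[[ct]] <- data.frame(contrast = ct, pattern = names(tab),
                                    n = as.integer(tab),
                                    proportion = as.numeric(tab) / denom,
                                    stringsAsFactors = FALSE)
  }
  intersection_counts <- if (length(counts_list)) do.call(rbind, counts_list)
                         else data.frame(contrast = character(), pattern = character(),
                                         n = integer(), proportion = numeric())
  rownames(intersection_counts) <- NULL

  has_up <- rowSums(uni[dir_cols] == "up") > 0
  has_down <- rowSums(uni[dir_cols] == "down") > 0
  conflicts <- uni[has_up & has_down, , drop = FALSE]
  rownames(conflicts) <- NULL

  structure(list(modes = modes, membership = membership,
                 n_universe = nrow(base) / length(unique(base$contrast)),
                 intersection_counts = intersection_counts,
                 conflicts = conflicts), class = "mode_comparison")
}

#' Summarize a mode comparison for intersection (upset-style) plotting
#'
#' Per contrast and direction, counts how many genes each combination of
#' modes calls in that direction, with percentages relative to all genes
#' differentially expressed in any mode for that contrast (the shared
#' denominator). Percentages across the full direction-pattern partition sum
#' to 100 within a contrast.
#'
#' @param cmp a [compare_modes()] result.
#' @return data.frame: contrast, direction, modes (label of the calling-mode
#'   combination), n, pct.
#' @export
summarize_comparison <- function(cmp) {
  dir_cols <- paste0("dir_", cmp$modes)
  mem <- cmp$membership
  any_de <- rowSums(mem[dir_cols] != "ns") > 0
  uni <- mem[any_de, , drop = FALSE]
  out <- list()
  for (ct in unique(mem$contrast)) {
    sub <- uni[uni$contrast == ct, , drop = FALSE]
    denom <- nrow(sub)
    if (!denom) next
    for (dir in c("up", "down")) {
      hit <- sub[dir_cols] == dir
      called <- rowSums(hit) > 0
      if (!any(called)) next
      combo <- apply(hit[called, , drop = FALSE], 1, function(z)
        paste(cmp$modes[z], collapse = "+"))
      tab <- table(combo)
      out[[paste(ct, dir)]] <- data.frame(
        contrast = ct, direction = dir, modes = names(tab), n = as.integer(tab),
        pct = 100 * as.numeric(tab) / denom, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contrast = character(), direction = character(),
                      modes = character(), n = integer(), pct = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contrast, res$direction, -res$n), ]
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("Cross-mode DE comparison over", x$n_universe, "genes\n")
  print(x$intersection_counts)
  cat(nrow(x$conflicts), "direction conflict(s)\n")
  invisible(x)
}
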