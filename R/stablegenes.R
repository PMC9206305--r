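#' Robust expression filter
#'
#' Genes whose count reaches `min_count` in every sample; only such robustly
#' expressed transcripts enter the stable-gene screen (default min count 30).
#'
#' @param counts gene x sample count matrix.
#' @param min_count minimum count per sample (default 30).
#' @return character vector of gene identifiers (possibly empty, with warning).
#' @export
robust_filter <- function(counts, min_count = 30) {
  keep <- rownames(counts)[apply(counts >= min_count, 1, all)]
  if (!length(keep))
    warning("no gene passes the robust expression filter (min_count = ", min_count, ")")
  keep
}

#' Screen and rank transcripts for within-participant stability
#'
#' For every gene, fits the random-intercept LMM ([fit_reml()]) of log-CPM on
#' the screening design; genes whose maximal absolute condition t-value is
#' below `t_threshold` (i.e. free from systematic condition effects) are
#' ranked by decreasing ICC, and the top `top_k` become the mode's stable
#' reference genes. ICC ties are broken by gene identifier for determinism.
#'
#' @param logcpm log-scale abundance matrix restricted to [robust_filter()]
#'   genes.
#' @param meta aligned metadata.
#' @param t_threshold screening threshold on max |t| (default 1.5).
#' @param top_k size of the stable set (default 10; all survivors with a
#'   warning if fewer pass).
#' @param include_volume,include_interactions forwarded to [screening_design()].
#' @return object of class `stable_gene_report`: `mode`, `screened`
#'   (data.frame: gene_id, max_t, icc, converged, passed_screen), `ranked`
#'   (survivors by decreasing ICC), `top_k` (character vector).
#' @export
screen_and_rank <- function(logcpm, meta, t_threshold = 1.5, top_k = 10,
                            include_volume = TRUE, include_interactions = TRUE) {
  X <- screening_design(meta, include_volume, include_interactions)
  cond_labels <- attr(X, "condition_labels")
  genes <- rownames(logcpm)
  m <- matrix(NA_real_, length(genes), 2, dimnames = list(genes, c("max_t", "icc")))
  converged <- logical(length(genes))
  for (i in seq_along(genes)) {
    fit <- tryCatch(fit_reml(logcpm[i, ], X, meta$participant),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged && all(is.finite(fit$t_values))) {
      m[i, ] <- c(condition_t_max(fit, cond_labels), fit$icc)
      converged[i] <- TRUE
    }
  }
  screened <- data.frame(gene_id = genes, max_t = m[, "max_t"], icc = m[, "icc"],
                         converged = converged,
                         passed_screen = converged & m[, "max_t"] < t_threshold,
                         row.names = NULL, stringsAsFactors = FALSE)
  if (any(!converged))
    warning(sum(!converged), " gene(s) failed to fit and were excluded from ranking")
  surv <- screened[screened$passed_screen, , drop = FALSE]
  if (!nrow(surv))
    stop("no transcript passed the stability screen (max |t| < ", t_threshold,
         "); consider relaxing the threshold")
  ranked <- surv[order(-surv$icc, surv$gene_id), , drop = FALSE]
  rownames(ranked) <- NULL
  if (nrow(ranked) < top_k)
    warning("only ", nrow(ranked), " transcripts passed the screen; using all of them ",
            "as the stable set (requested top_k = ", top_k, ")")
  structure(list(
    mode = attr(logcpm, "mode_label"),
    t_threshold = t_threshold,
    screened = screened,
    ranked = ranked,
    top_k = utils::head(ranked$gene_id, top_k)
  ), class = "stable_gene_report")
}

#' @export
print.stable_gene_report <- function(x, ...) {
  cat(sprintf("Stable-gene report (%s): %d screened, %d passed max |t| < %g\n",
              if (is.null(x$mode)) "?" else x$mode, nrow(x$screened),
              sum(x$screened$passed_screen), x$t_threshold))
  cat("top stable set:", paste(x$top_k, collapse = ", "), "\n")
  invisible(x)
}

#' Stable-gene sample reference
#'
#' Each stable gene's abundance profile is scaled by its maximum across
#' samples (`x / max(x)`, so each profile peaks at exactly 1) and the scaled
#' profiles are averaged per sample. The input must be on a common,
#' count-proportional linear scale across the compared samples (the pipeline
#' uses raw counts): a mode's stable genes then estimate that mode's
#' effective denominator per sample, and the reference lies in (0, 1], giving
#' finite log offsets for the count models.
#'
#' @param abund gene x sample matrix on a linear scale.
#' @param stable_set identifiers of the stable genes (non-empty; genes with
#'   all-zero profiles are excluded with a warning).
#' @return object of class `sample_reference`: data.frame with `sample_id`,
#'   `reference`; attributes `genes`, `mode`.
#' @export
sample_reference <- function(abund, stable_set) {
  if (!length(stable_set)) stop("stable_set must be non-empty")
  if (isTRUE(attr(abund, "log_transformed")))
    stop("sample_reference expects a linear-scale matrix")
  missing <- setdiff(stable_set, rownames(abund))
  if (length(missing))
    stop("stable gene(s) absent from the abundance matrix: ",
         paste(missing, collapse = ", "))
  v <- abund[stable_set, , drop = FALSE]
  mx <- apply(v, 1, max)
  if (any(mx == 0)) {
    warning("stable gene(s) with all-zero profile excluded: ",
            paste(stable_set[mx == 0], collapse = ", "))
    v <- v[mx > 0, , drop = FALSE]
    mx <- mx[mx > 0]
    if (!nrow(v)) stop("all stable genes have zero profiles")
  }
  ref <- colMeans(v / mx)
  structure(data.frame(sample_id = colnames(abund), reference = ref,
                       row.names = NULL, stringsAsFactors = FALSE),
            genes = rownames(v), mode = attr(abund, "mode_label"),
            class = c("sample_reference", "data.frame"))
}

#' Between-mode reference-ratio analysis
#'
#' Models the log ratio of two sample references over time with a participant
#' random intercept. Per time level it reports the exponentiated estimated
#' mean ratio (`fold_change`, the ratio's level at that time) and the change
#' relative to baseline (`fold_change_vs_baseline`, 1 at baseline by
#' construction), each with a Wald 95% CI (estimate +/- 1.96 SE on the log
#' scale). A baseline-relative rise above 1 means the numerator mode's stable
#' genes gain abundance relative to the denominator mode's over the
#' intervention, the signature of global transcriptome amplification.
#'
#' @param ref_num,ref_den [sample_reference()] objects covering the same
#'   samples.
#' @param meta aligned metadata.
#' @return data.frame of class `ratio_estimate` with one row per time level:
#'   `time`, `fold_change`, `ci_low`, `ci_high`, `fold_change_vs_baseline`,
#'   `ci_low_vs_baseline`, `ci_high_vs_baseline`; numerator/denominator mode
#'   attributes.
#' @export
reference_ratio <- function(ref_num, ref_den, meta) {
  if (!setequal(ref_num$sample_id, ref_den$sample_id))
    stop("reference sets cover different samples")
  den <- ref_den$reference[match(ref_num$sample_id, ref_den$sample_id)]
  mmeta <- meta[match(ref_num$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(mmeta$sample_id)) stop("reference samples absent from metadata")
  y <- log(ref_num$reference / den)
  time <- if (is.factor(mmeta$time)) droplevels(mmeta$time) else factor(mmeta$time)
  lvls <- levels(time)
  if (stats::var(y) < 1e-20) {
    lv <- exp(mean(y))
    out <- data.frame(time = lvls, fold_change = lv, ci_low = lv, ci_high = lv,
                      fold_change_vs_baseline = 1, ci_low_vs_baseline = 1,
                      ci_high_vs_baseline = 1, stringsAsFactors = FALSE)
  } else {
    X <- stats::model.matrix(~time, data.frame(time = time))
    fit <- fit_reml(y, X, mmeta$participant)
    cf <- c(0, fit$coefficients[paste0("time", lvls[-1])])       # vs baseline
    se_cf <- c(0, fit$standard_errors[paste0("time", lvls[-1])])
    lvl <- fit$coefficients["(Intercept)"] + cf                  # per-time mean
    se_lvl <- vapply(seq_along(lvls), function(i) {
      if (i == 1) return(fit$standard_errors["(Intercept)"])
      idx <- c("(Intercept)", paste0("time", lvls[i]))
      sqrt(sum(fit$vcov[idx, idx]))
    }, numeric(1))
    out <- data.frame(
      time = lvls,
      fold_change = exp(lvl),
      ci_low = exp(lvl - 1.96 * se_lvl),
      ci_high = exp(lvl + 1.96 * se_lvl),
      fold_change_vs_baseline = exp(cf),
      ci_low_vs_baseline = exp(cf - 1.96 * se_cf),
      ci_high_vs_baseline = exp(cf + 1.96 * se_cf),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(out, numerator_mode = attr(ref_num, "mode"),
            denominator_mode = attr(ref_den, "mode"),
            class = c("ratio_estimate", "data.frame"))
}
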