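#' @title Normalization modes
#' @description The three viewpoints under which counts are modeled:
#'   `"per_library_size"` (counts relative to TMM-scaled library size, the
#'   compositional viewpoint), `"per_total_rna"` (counts relative to the fixed
#'   total-RNA input), and `"per_sample_size"` (counts relative to mg of
#'   tissue).
#' @export
NORMALIZATION_MODES <- c("per_library_size", "per_total_rna", "per_sample_size")

#' Per-sample library sizes
#'
#' @param counts gene x sample count matrix.
#' @return named vector of column sums; errors on all-zero samples.
#' @export
library_sizes <- function(counts) {
  ls <- colSums(counts)
  if (any(ls <= 0))
    stop("degenerate sample(s) with zero total counts: ",
         paste(colnames(counts)[ls <= 0], collapse = ", "))
  ls
}

# upper-quartile reference selection: sample whose upper-quartile proportion
# is closest to the mean upper-quartile proportion
.tmm_ref_sample <- function(counts, lib) {
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  which.min(abs(uq - mean(uq)))
}

# one sample vs reference: doubly trimmed, precision-weighted mean of M values
.tmm_one <- function(obs, ref, n_obs, n_ref, trim_m, trim_a, min_count) {
  keep <- obs >= min_count & ref >= min_count
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(NA_real_)
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- (log2(p_obs) + log2(p_ref)) / 2
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  fin <- is.finite(M) & is.finite(A) & is.finite(w)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (!n) return(NA_real_)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(NA_real_)
  2^(sum(M[keep2] * w[keep2]) / sum(w[keep2]))
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-sample scaling factors computed from doubly trimmed,
#' precision-weighted log2 ratios of gene proportions against a reference
#' sample. For each sample, gene-wise M (log2 ratio of library-size-normalized
#' proportions) and A (average log2 proportion) are computed over genes
#' expressed in both sample and reference; the top and bottom `trim_m` of M
#' and `trim_a` of A are trimmed; the factor is 2 to the inverse-variance
#' weighted mean of the surviving M values (weights from the asymptotic
#' binomial variance of M). Factors are rescaled to geometric mean 1. When no
#' reference is given, the sample whose upper-quartile proportion is closest
#' to the mean upper-quartile is used.
#'
#' @param counts gene x sample count matrix with >= 2 samples.
#' @param ref_sample optional reference sample (name or column index).
#' @param trim_m fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A values trimmed from each tail (default 0.05).
#' @param min_count genes must have at least this count in both sample and
#'   reference to enter the trimming (default 1).
#' @return named vector of scaling factors, geometric mean 1. Samples for
#'   which no gene survives trimming fall back to factor 1 with a warning.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05,
                        min_count = 1) {
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples")
  lib <- library_sizes(counts)
  ref <- if (is.null(ref_sample)) .tmm_ref_sample(counts, lib)
         else if (is.character(ref_sample)) match(ref_sample, colnames(counts))
         else as.integer(ref_sample)
  if (is.na(ref) || ref < 1 || ref > ncol(counts)) stop("unknown reference sample")
  f <- vapply(seq_len(ncol(counts)), function(s)
    .tmm_one(counts[, s], counts[, ref], lib[s], lib[ref], trim_m, trim_a, min_count),
    numeric(1))
  if (anyNA(f)) {
    warning("no genes survived trimming for sample(s) ",
            paste(colnames(counts)[is.na(f)], collapse = ", "),
            "; falling back to factor 1")
    f[is.na(f)] <- 1
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Per-sample denominators for a normalization mode
#'
#' Builds the denominator set D_s of a mode: TMM-scaled library size
#' (`per_library_size`), the constant 1e6 standing for the fixed total-RNA
#' input (`per_total_rna`), or tissue mass x 1e6 (`per_sample_size`).
#'
#' @param counts gene x sample count matrix.
#' @param meta aligned metadata (see [validate_design()]).
#' @param mode one of [NORMALIZATION_MODES].
#' @param factors TMM factors, required iff `mode = "per_library_size"`.
#' @param depth_rescale for `per_total_rna` only: additionally divide by
#'   relative sequencing depth (library size / mean library size). Default
#'   FALSE, i.e. raw counts stand for abundance per unit total RNA.
#' @return data.frame of class `denominator_set` with columns `sample_id`,
#'   `mode`, `denominator` and the components that apply.
#' @export
denominators <- function(counts, meta, mode = NORMALIZATION_MODES, factors = NULL,
                         depth_rescale = FALSE) {
  mode <- match.arg(mode)
  sid <- colnames(counts)
  out <- data.frame(sample_id = sid, mode = mode, denominator = NA_real_,
                    stringsAsFactors = FALSE)
  if (mode == "per_library_size") {
    if (is.null(factors)) stop("per_library_size denominators require TMM factors")
    if (is.null(names(factors)) || !all(sid %in% names(factors)))
      stop("TMM factors must be named for every sample")
    lib <- library_sizes(counts)
    out$lib_size <- lib
    out$tmm_factor <- factors[sid]
    out$denominator <- lib * factors[sid]
  } else if (mode == "per_total_rna") {
    out$denominator <- rep(1e6, length(sid))
    if (depth_rescale) {
      lib <- library_sizes(counts)
      out$lib_size <- lib
      out$denominator <- out$denominator * lib / mean(lib)
    }
  } else {
    if (is.null(meta$tissue_mass_mg)) stop("per_sample_size requires tissue_mass_mg in metadata")
    m <- meta$tissue_mass_mg[match(sid, meta$sample_id)]
    if (anyNA(m)) stop("tissue_mass_mg missing for sample(s): ",
                       paste(sid[is.na(m)], collapse = ", "))
    out$tissue_mass_mg <- m
    out$denominator <- m * 1e6
  }
  if (any(out$denominator <= 0)) stop("denominators must be positive")
  class(out) <- c("denominator_set", "data.frame")
  out
}

#' Counts per million-scale abundance
#'
#' `value[g, s] = count[g, s] / D_s * 1e6` (the 1e6 restores CPM magnitude and
#' is optional; all within-gene model statistics are invariant to it).
#'
#' @param counts gene x sample count matrix.
#' @param denom a [denominators()] result aligned to `counts`.
#' @param million_scale multiply by 1e6 (default TRUE).
#' @return gene x sample abundance matrix with attributes `mode`,
#'   `log_transformed` (FALSE).
#' @export
cpm <- function(counts, denom, million_scale = TRUE) {
  if (!identical(denom$sample_id, colnames(counts)))
    stop("denominator set does not align with count columns")
  v <- sweep(counts, 2, denom$denominator, `/`)
  if (million_scale) v <- v * 1e6
  structure(v, mode_label = denom$mode[1], log_transformed = FALSE, log_base = NA_real_)
}

#' Log-transform an abundance matrix
#'
#' @param abund a [cpm()] result (linear scale).
#' @param base logarithm base (default natural log; downstream t-values and
#'   ICCs are invariant to the base).
#' @param pseudocount added before the log (default 0; zero values with
#'   pseudocount 0 error, pointing to the robust expression filter).
#' @return log-scale abundance matrix with `log_transformed = TRUE`.
#' @export
log_cpm <- function(abund, base = exp(1), pseudocount = 0) {
  if (isTRUE(attr(abund, "log_transformed"))) stop("abundance matrix is already on the log scale")
  if (pseudocount == 0 && any(abund == 0))
    stop("zero abundance with pseudocount 0; apply the robust expression filter first ",
         "(see robust_filter) or set a pseudocount")
  v <- log(abund + pseudocount, base = base)
  structure(v, mode_label = attr(abund, "mode_label"), log_transformed = TRUE,
            log_base = base)
}
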