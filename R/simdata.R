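#' Default simulation parameters for a synthetic training study
#'
#' Returns the parameter set describing the emulated study: 25 participants,
#' two legs per participant (low / moderate training volume, treated as
#' biological replicates), three biopsy time points (weeks 0, 2 and 12), a
#' fixed 1000 ng total-RNA library input, and a global total-RNA amplification
#' of +27% at week 2 and +17% at week 12 relative to baseline.
#'
#' The generator distinguishes the total-RNA amplification `amplification_per_time`
#' (A_t, total RNA per mg tissue) from the mRNA-pool amplification
#' `mrna_amplification_per_time` (G_t, messenger pool per mg tissue). Keeping
#' G_t above A_t makes the three normalization viewpoints pairwise distinct:
#' genes with a constant mRNA-pool share then rise when expressed per unit
#' total RNA, and rise even more when expressed per mg tissue.
#'
#' @param ... named overrides of any default parameter (unknown names error).
#'
#' @section Parameters:
#' \describe{
#'   \item{n_participants, legs_per_participant, time_labels}{study dimensions;
#'     `time_labels[1]` is the baseline level.}
#'   \item{n_genes}{number of simulated transcripts.}
#'   \item{amplification_per_time}{A_t, total RNA per mg relative to baseline
#'     (first element must be 1).}
#'   \item{mrna_amplification_per_time}{G_t, mRNA pool per mg relative to
#'     baseline (first element must be 1).}
#'   \item{rna_input_ng}{fixed total-RNA mass loaded per library (ng).}
#'   \item{tissue_mass_meanlog, tissue_mass_sdlog}{log-normal baseline-equivalent
#'     tissue requirement (mg); the recorded mass is divided by the realized
#'     RNA yield factor, emulating that less tissue is needed once yield per
#'     mg rises.}
#'   \item{depth_meanlog, depth_sdlog}{log-normal sequencing-depth budget
#'     (reads); the realized library size additionally tracks the mRNA
#'     fraction of the fixed input.}
#'   \item{baseline_log_abundance_mean, baseline_log_abundance_sd}{mean / sd of
#'     per-gene baseline log abundance alpha_g.}
#'   \item{participant_sd_range, stable_participant_sd_range}{uniform ranges
#'     for the gene-wise participant random-intercept sd sigma_u; designated
#'     stable classes draw from the second (higher) range, which is what makes
#'     them high-ICC reference-gene candidates.}
#'   \item{dispersion_meanlog, dispersion_sdlog}{log-normal gene-wise NB
#'     dispersion phi (variance = mu + phi mu^2).}
#'   \item{fraction_tissue_stable, fraction_totalrna_stable,
#'     fraction_library_stable, fraction_de}{gene-class proportions; the
#'     remainder is background.}
#'   \item{de_effect_sd}{sd of per-mg log fold-changes of the de class.}
#'   \item{background_wobble_sd}{sd of per-gene, per-time deviations of
#'     background genes around the global mRNA amplification.}
#'   \item{rna_yield_noise_sd}{sd of log-normal noise on total-RNA yield per mg.}
#'   \item{volume_effect}{log-scale shift of de-class genes in the
#'     moderate-volume leg (default 0: legs are exchangeable replicates).}
#' }
#'
#' @return an object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params()
#' p$n_participants
#' p2 <- sim_params(n_genes = 200, fraction_de = 0)
#' @export
sim_params <- function(...) {
  p <- list(
    n_participants = 25L,
    legs_per_participant = 2L,
    time_labels = c("week0", "week2", "week12"),
    n_genes = 2000L,
    amplification_per_time = c(1, 1.27, 1.17),
    mrna_amplification_per_time = c(1, 1.6, 1.4),
    rna_input_ng = 1000,
    tissue_mass_meanlog = log(25),
    tissue_mass_sdlog = 0.10,
    depth_meanlog = log(5e6),
    depth_sdlog = 0.20,
    baseline_log_abundance_mean = 4,
    baseline_log_abundance_sd = 1.2,
    participant_sd_range = c(0.05, 0.20),
    stable_participant_sd_range = c(0.30, 0.50),
    dispersion_meanlog = log(0.02),
    dispersion_sdlog = 0.40,
    fraction_tissue_stable = 0.05,
    fraction_totalrna_stable = 0.05,
    fraction_library_stable = 0.05,
    fraction_de = 0.10,
    de_effect_sd = 0.5,
    background_wobble_sd = 0.15,
    rna_yield_noise_sd = 0.15,
    volume_effect = 0
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all simulation parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

#' @rdname sim_params
#' @export
default_params <- function() sim_params()

#' Validate a simulation parameter set
#'
#' Checks the structural invariants of a [sim_params()] object and errors with
#' the name of the offending field.
#'
#' @param params a `sim_params` object (or named list with the same fields).
#' @return `params`, invisibly, if valid.
#' @export
validate_sim_params <- function(params) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid simulation parameter '", field, "': ", msg,
                          call. = FALSE)
  }
  nt <- length(params$time_labels)
  chk(is.numeric(params$n_participants) && params$n_participants >= 2,
      "n_participants", "must be >= 2")
  chk(is.numeric(params$n_genes) && params$n_genes >= 2, "n_genes", "must be >= 2")
  chk(params$legs_per_participant >= 1, "legs_per_participant", "must be >= 1")
  chk(nt >= 2 && !anyDuplicated(params$time_labels), "time_labels",
      "needs >= 2 distinct levels")
  for (f in c("amplification_per_time", "mrna_amplification_per_time")) {
    a <- params[[f]]
    chk(length(a) == nt, f, sprintf("needs one value per time point (%d)", nt))
    chk(all(a > 0), f, "must be positive")
    chk(isTRUE(all.equal(a[1], 1)), f, "baseline value must be 1")
  }
  frs <- c("fraction_tissue_stable", "fraction_totalrna_stable",
           "fraction_library_stable", "fraction_de")
  for (f in frs) chk(params[[f]] >= 0 && params[[f]] <= 1, f, "must be in [0, 1]")
  chk(sum(unlist(params[frs])) <= 1, "fraction_de",
      "gene-class fractions must sum to <= 1")
  chk(params$rna_input_ng > 0, "rna_input_ng", "must be positive")
  chk(params$de_effect_sd >= 0, "de_effect_sd", "must be >= 0")
  chk(params$rna_yield_noise_sd >= 0, "rna_yield_noise_sd", "must be >= 0")
  chk(params$background_wobble_sd >= 0, "background_wobble_sd", "must be >= 0")
  for (f in c("participant_sd_range", "stable_participant_sd_range")) {
    r <- params[[f]]
    chk(length(r) == 2 && all(r >= 0) && r[1] <= r[2], f,
        "must be a non-negative increasing range")
  }
  chk(params$tissue_mass_sdlog >= 0, "tissue_mass_sdlog", "must be >= 0")
  chk(params$depth_sdlog >= 0, "depth_sdlog", "must be >= 0")
  invisible(params)
}

# gene-class labels in assignment order; remainder is background
.sim_classes <- c("tissue_stable", "totalrna_stable", "library_stable", "de")

# per-mg true abundance matrix T[g, s]: exp(alpha + u + delta + volume term)
.sim_true_abundance <- function(alpha, u, delta, volume_log_fc,
                                participant_idx, time_idx, moderate) {
  eta <- alpha + u[, participant_idx, drop = FALSE] +
    delta[, time_idx, drop = FALSE] +
    outer(volume_log_fc, as.numeric(moderate))
  exp(eta)
}

#' Simulate a repeated-measures RNA-seq study with known three-viewpoint truth
#'
#' Generates counts from a compositional model of library preparation with a
#' fixed total-RNA input. Per-mg true abundance is
#' \eqn{T_{gs} = \exp(\alpha_g + u_{g,p(s)} + \delta_{g,t(s)})}, the mRNA pool
#' per mg is \eqn{M_s = \sum_g T_{gs}}, the total-RNA yield per mg is
#' \eqn{Y_s \propto A_{t(s)} \eta_s} with log-normal noise \eqn{\eta_s}, and
#' the realized library size is \eqn{L_s = D_s M_s / (A_{t(s)} \eta_s M_{ref})}
#' (depth budget times the mRNA fraction of the fixed input). Expected counts
#' are \eqn{\mu_{gs} = L_s T_{gs} / M_s} and counts are drawn
#' NB(mean \eqn{\mu}, variance \eqn{\mu + \phi_g \mu^2}). The recorded tissue
#' mass is the amount needed to supply the fixed RNA input,
#' \eqn{mg_s = mg^{base}_s / (A_{t(s)} \eta_s)}.
#'
#' Gene classes (see [sim_params()]): `tissue_stable` genes have
#' \eqn{\delta = 0} (constant per-mg abundance), `totalrna_stable` genes track
#' the total-RNA amplification (\eqn{\delta = \log A_t}), `library_stable`
#' genes keep a constant mRNA-pool share (\eqn{\delta = \log G_t}), `de` genes
#' draw independent per-time log fold-changes, and background genes follow the
#' global mRNA amplification with per-gene wobble.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; identical `(params, seed)` give bit-identical output.
#' @return an object of class `sim_study`: a list with `counts` (integer
#'   gene x sample matrix), `metadata` (data.frame: sample_id, participant,
#'   time, condition, tissue_mass_mg, rna_input_ng), `truth` (gene classes,
#'   per-viewpoint log fold-change matrices, participant intercepts,
#'   dispersions, per-sample denominator truth), and `params_used`.
#' @seealso [expected_counts()] for the analytic mean used by the sampler.
#' @examples
#' st <- simulate_study(sim_params(n_genes = 50, n_participants = 4), seed = 1)
#' dim(st$counts)
#' table(st$truth$gene_class)
#' @export
simulate_study <- function(params = sim_params(), seed = 1L) {
  validate_sim_params(params)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))

  G <- as.integer(params$n_genes)
  P <- as.integer(params$n_participants)
  nleg <- as.integer(params$legs_per_participant)
  tl <- params$time_labels
  nt <- length(tl)
  A <- params$amplification_per_time
  Gamp <- params$mrna_amplification_per_time

  conds <- c("low", "moderate", paste0("leg", seq_len(max(0, nleg - 2)) + 2))[seq_len(nleg)]
  meta <- expand.grid(condition = conds, time = tl, participant = sprintf("P%02d", seq_len(P)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("participant", "time", "condition")]
  meta$time <- factor(meta$time, levels = tl)
  meta$sample_id <- sprintf("%s_%s_%s", meta$participant, meta$condition, meta$time)
  S <- nrow(meta)
  time_idx <- as.integer(meta$time)
  part_idx <- match(meta$participant, unique(meta$participant))
  moderate <- meta$condition == "moderate"

  # gene classes, assigned deterministically in blocks
  n_cls <- vapply(c("fraction_tissue_stable", "fraction_totalrna_stable",
                    "fraction_library_stable", "fraction_de"),
                  function(f) as.integer(round(params[[f]] * G)), integer(1))
  gene_class <- rep("background", G)
  pos <- 0L
  for (i in seq_along(.sim_classes)) {
    if (n_cls[i] > 0) gene_class[pos + seq_len(n_cls[i])] <- .sim_classes[i]
    pos <- pos + n_cls[i]
  }
  gene_ids <- sprintf("gene%04d", seq_len(G))
  stable_cls <- gene_class %in% c("tissue_stable", "totalrna_stable", "library_stable")

  # gene-level parameters
  alpha <- stats::rnorm(G, params$baseline_log_abundance_mean,
                        params$baseline_log_abundance_sd)
  sigma_u <- stats::runif(G, params$participant_sd_range[1], params$participant_sd_range[2])
  sigma_u[stable_cls] <- stats::runif(sum(stable_cls),
                                      params$stable_participant_sd_range[1],
                                      params$stable_participant_sd_range[2])
  phi <- stats::rlnorm(G, params$dispersion_meanlog, params$dispersion_sdlog)

  # per-mg log fold-changes delta[g, t] (baseline column exactly 0)
  delta <- matrix(0, G, nt, dimnames = list(gene_ids, tl))
  for (t in 2:nt) {
    delta[gene_class == "totalrna_stable", t] <- log(A[t])
    delta[gene_class == "library_stable", t] <- log(Gamp[t])
    nde <- sum(gene_class == "de")
    delta[gene_class == "de", t] <- stats::rnorm(nde, 0, params$de_effect_sd)
    nbg <- sum(gene_class == "background")
    delta[gene_class == "background", t] <-
      log(Gamp[t]) + stats::rnorm(nbg, 0, params$background_wobble_sd)
  }
  volume_log_fc <- rep(0, G)
  volume_log_fc[gene_class == "de"] <- params$volume_effect

  u <- matrix(stats::rnorm(G * P, 0, rep(sigma_u, P)), G, P,
              dimnames = list(gene_ids, unique(meta$participant)))

  # sample-level physical quantities
  eta <- exp(stats::rnorm(S, 0, params$rna_yield_noise_sd))   # RNA-yield noise
  yield_base <- 40                                            # ng total RNA per mg at baseline
  Y <- yield_base * A[time_idx] * eta                         # total RNA per mg
  mg_base <- exp(stats::rnorm(S, params$tissue_mass_meanlog, params$tissue_mass_sdlog))
  tissue_mass_mg <- mg_base / (A[time_idx] * eta)             # tissue used for fixed input
  depth <- exp(stats::rnorm(S, params$depth_meanlog, params$depth_sdlog))

  Tmat <- .sim_true_abundance(alpha, u, delta, volume_log_fc, part_idx, time_idx, moderate)
  M <- colSums(Tmat)                                          # mRNA pool per mg
  M_ref <- sum(exp(alpha + sigma_u^2 / 2))                    # expected baseline pool
  L <- depth * M / (A[time_idx] * eta * M_ref)                # realized library size

  mu <- sweep(Tmat, 2, L / M, `*`)
  counts <- matrix(stats::rnbinom(G * S, mu = as.vector(mu), size = rep(1 / phi, S)),
                   G, S, dimnames = list(gene_ids, meta$sample_id))
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"

  # viewpoint truths: expected pool ratio uses E[T] = exp(alpha + sigma_u^2/2 + delta)
  e_pool <- colSums(exp(alpha + sigma_u^2 / 2 + delta))
  pool_ratio <- e_pool / e_pool[1]
  per_library <- sweep(delta, 2, log(pool_ratio), `-`)
  per_totalrna <- sweep(delta, 2, log(A), `-`)

  truth <- list(
    gene_class = stats::setNames(gene_class, gene_ids),
    baseline_log_abundance = stats::setNames(alpha, gene_ids),
    participant_sd = stats::setNames(sigma_u, gene_ids),
    dispersion = stats::setNames(phi, gene_ids),
    per_mg_log_fc = delta,
    per_library_log_fc = per_library,
    per_total_rna_log_fc = per_totalrna,
    volume_log_fc = stats::setNames(volume_log_fc, gene_ids),
    participant_intercepts = u,
    pool_ratio = stats::setNames(pool_ratio, tl),
    sample_denominator_truth = data.frame(
      sample_id = meta$sample_id, mrna_pool_per_mg = M, rna_yield_per_mg = Y,
      library_size = L, depth_draw = depth, yield_noise = eta,
      row.names = NULL, stringsAsFactors = FALSE
    )
  )

  metadata <- data.frame(
    sample_id = meta$sample_id, participant = meta$participant, time = meta$time,
    condition = meta$condition, tissue_mass_mg = tissue_mass_mg,
    rna_input_ng = params$rna_input_ng, row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(counts = counts, metadata = metadata, truth = truth,
                 params_used = params), class = "sim_study")
}

#' Redraw counts for an existing simulated study
#'
#' Holds the study's truth (abundances, denominators, dispersions) fixed and
#' redraws only the negative binomial counting noise. Useful for Monte-Carlo
#' checks against [expected_counts()].
#'
#' @param study a [simulate_study()] result.
#' @param seed integer seed for the redraw.
#' @return the study with a fresh `counts` matrix.
#' @export
resample_counts <- function(study, seed) {
  stopifnot(inherits(study, "sim_study"))
  set.seed(as.integer(seed))
  mu <- expected_counts(study$params_used, study$truth, study$metadata)
  phi <- study$truth$dispersion
  study$counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                        size = rep(1 / phi, ncol(mu))),
                         nrow(mu), ncol(mu), dimnames = dimnames(mu))
  if (max(study$counts) < .Machine$integer.max) storage.mode(study$counts) <- "integer"
  study
}

#' Expected counts under the simulation model
#'
#' Analytic per-gene, per-sample expected count
#' \eqn{\mu_{gs} = L_s T_{gs} / M_s}, exactly as used by the sampler in
#' [simulate_study()]. Serves as the oracle for Monte-Carlo checks.
#'
#' @param params the `sim_params` used (for the volume-effect term).
#' @param truth the `truth` component of a [simulate_study()] result.
#' @param metadata the matching `metadata` data.frame.
#' @return gene x sample matrix of expected counts; columns sum exactly to the
#'   true library sizes.
#' @export
expected_counts <- function(params, truth, metadata) {
  alpha <- truth$baseline_log_abundance
  u <- truth$participant_intercepts
  delta <- truth$per_mg_log_fc
  sdt <- truth$sample_denominator_truth
  if (!identical(sdt$sample_id, metadata$sample_id))
    stop("metadata and truth describe different samples")
  if (!identical(rownames(u), names(alpha)) ||
      !identical(rownames(delta), names(alpha)))
    stop("truth components have mismatched gene sets")
  part_idx <- match(metadata$participant, colnames(u))
  if (anyNA(part_idx)) stop("metadata participants absent from truth")
  time_idx <- match(as.character(metadata$time), colnames(delta))
  if (anyNA(time_idx)) stop("metadata time levels absent from truth")
  moderate <- metadata$condition == "moderate"
  Tmat <- .sim_true_abundance(alpha, u, delta, truth$volume_log_fc,
                              part_idx, time_idx, moderate)
  M <- colSums(Tmat)
  mu <- sweep(Tmat, 2, sdt$library_size / M, `*`)
  dimnames(mu) <- list(names(alpha), metadata$sample_id)
  mu
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic repeated-measures RNA-seq study\n")
  cat(sprintf("  %d genes x %d samples (%d participants, %d legs, %d time points)\n",
              nrow(x$counts), ncol(x$counts), x$params_used$n_participants,
              x$params_used$legs_per_participant, length(x$params_used$time_labels)))
  cat("  gene classes:", paste(sprintf("%s=%d", names(table(x$truth$gene_class)),
                                       table(x$truth$gene_class)), collapse = ", "), "\n")
  invisible(x)
}
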