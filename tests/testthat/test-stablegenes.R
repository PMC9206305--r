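test_that("robust filter keeps genes at or above the threshold in every sample", {
  m <- rbind(kept = c(30L, 30L, 31L), dropped = c(30L, 29L, 100L))
  colnames(m) <- paste0("s", 1:3)
  expect_identical(robust_filter(m, 30), "kept")
  set.seed(7)
  r <- matrix(rpois(1000, 40), 100, 10,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:10)))
  brute <- rownames(r)[vapply(seq_len(nrow(r)),
                              function(i) all(r[i, ] >= 30), logical(1))]
  expect_identical(robust_filter(r, 30), brute)
})

test_that("screen excludes strong condition effects and keeps identical genes adjacent", {
  st <- simulate_study(sim_params(n_genes = 60, n_participants = 8,
                                  amplification_per_time = c(1, 1, 1),
                                  mrna_amplification_per_time = c(1, 1, 1),
                                  fraction_de = 0, background_wobble_sd = 0),
                       seed = 31)
  al <- validate_design(st$counts, st$metadata)
  keep <- robust_filter(al$counts, 5)
  d <- denominators(al$counts, al$meta, "per_total_rna")
  lc <- log_cpm(cpm(al$counts[keep, , drop = FALSE] + 1L, d))
  # inject a week-2 shift of 10 residual SDs into one gene
  shifted <- lc
  g1 <- keep[1]
  base_fit <- fit_reml(lc[g1, ], screening_design(al$meta), al$meta$participant)
  shift <- 10 * sqrt(base_fit$var_residual)
  shifted[g1, al$meta$time == "week2"] <- shifted[g1, al$meta$time == "week2"] + shift
  rep <- suppressWarnings(screen_and_rank(shifted, al$meta))
  row <- rep$screened[rep$screened$gene_id == g1, ]
  expect_gte(row$max_t, 1.5)
  expect_false(row$passed_screen)
  expect_false(g1 %in% rep$top_k)
  # duplicated gene rows tie in ICC and sort deterministically by identifier
  dup <- lc[c(2, 2), , drop = FALSE]
  rownames(dup) <- c("zzz_copy", "aaa_copy")
  rep2 <- suppressWarnings(screen_and_rank(rbind(lc, dup), al$meta))
  rk <- rep2$ranked
  i1 <- which(rk$gene_id == "aaa_copy"); i2 <- which(rk$gene_id == "zzz_copy")
  # the tied block (the two copies plus the original gene between them)
  # is contiguous and ordered lexicographically
  if (length(i1) && length(i2)) {
    block <- rk[i1:i2, ]
    expect_true(all(abs(block$icc - block$icc[1]) < 1e-12))
    expect_identical(block$gene_id, sort(block$gene_id))
  }
})

test_that("raising the t threshold never shrinks the survivor set", {
  st <- simulate_study(sim_params(n_genes = 80, n_participants = 6), seed = 33)
  al <- validate_design(st$counts, st$metadata)
  keep <- robust_filter(al$counts, 5)
  d <- denominators(al$counts, al$meta, "per_total_rna")
  lc <- log_cpm(cpm(al$counts[keep, , drop = FALSE] + 1L, d))
  reps <- lapply(c(0.8, 1.5, 3), function(th)
    suppressWarnings(tryCatch(screen_and_rank(lc, al$meta, t_threshold = th),
                              error = function(e) NULL)))
  surv <- lapply(reps, function(r)
    if (is.null(r)) character() else r$screened$gene_id[r$screened$passed_screen])
  expect_true(all(surv[[1]] %in% surv[[2]]))
  expect_true(all(surv[[2]] %in% surv[[3]]))
})

test_that("sample reference max-scales each stable gene and averages", {
  m <- rbind(g1 = c(2, 4, 4), g2 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  r1 <- sample_reference(m, "g1")
  expect_equal(r1$reference, c(0.5, 1, 1))
  r2 <- sample_reference(m, "g2")            # constant gene contributes 1
  expect_equal(r2$reference, rep(1, 3))
  both <- sample_reference(m, c("g1", "g2"))
  expect_equal(both$reference, c(0.75, 1, 1))
  expect_true(all(both$reference > 0 & both$reference <= 1))
  # brute force on random genes
  set.seed(12)
  rm <- matrix(runif(50, 1, 100), 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  rr <- sample_reference(rm, rownames(rm))
  brute <- colMeans(t(apply(rm, 1, function(x) x / max(x))))
  expect_equal(rr$reference, unname(brute))
  # invariance to rescaling one gene's profile
  rm2 <- rm; rm2[3, ] <- rm2[3, ] * 40
  expect_equal(sample_reference(rm2, rownames(rm2))$reference, rr$reference)
  # all-zero profile excluded with warning
  rm3 <- rm; rm3[1, ] <- 0
  expect_warning(r3 <- sample_reference(rm3, rownames(rm3)), "all-zero")
  expect_length(attr(r3, "genes"), 9)
})

test_that("reference ratios: identity gives fold-change one, constants propagate", {
  st <- simulate_study(sim_params(n_genes = 20, n_participants = 4), seed = 41)
  al <- validate_design(st$counts, st$metadata)
  cm <- al$counts
  ref <- sample_reference(cm, rownames(cm)[1:5])
  rr <- reference_ratio(ref, ref, al$meta)
  expect_equal(rr$fold_change, rep(1, 3))
  expect_equal(rr$fold_change_vs_baseline, rep(1, 3))
  expect_true(all(rr$ci_low <= 1 & rr$ci_high >= 1))
  ref2 <- ref; ref2$reference <- ref2$reference / 2
  rr2 <- reference_ratio(ref, ref2, al$meta)
  expect_equal(rr2$fold_change, rep(2, 3), tolerance = 1e-9)
  expect_equal(rr2$fold_change_vs_baseline, rep(1, 3), tolerance = 1e-9)
  ref3 <- ref; ref3$sample_id[1] <- "nope"
  expect_error(reference_ratio(ref, ref3[-1, ], al$meta), "different samples")
})

test_that("with amplification, the library-stable reference rises against the tissue-stable one", {
  st <- simulate_study(sim_params(n_genes = 400, n_participants = 10), seed = 47)
  al <- validate_design(st$counts, st$metadata)
  cls <- st$truth$gene_class
  lib_genes <- names(cls)[cls == "library_stable"][1:10]
  tis_genes <- names(cls)[cls == "tissue_stable"][1:10]
  ref_lib <- sample_reference(al$counts, lib_genes)
  ref_tis <- sample_reference(al$counts, tis_genes)
  rr <- reference_ratio(ref_lib, ref_tis, al$meta)
  wk2 <- rr[rr$time == "week2", ]
  expect_gt(wk2$fold_change_vs_baseline, 1)
  expect_gt(wk2$ci_low_vs_baseline, 1)
})
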