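test_that("default parameters mirror the emulated study design", {
  p <- sim_params()
  expect_equal(p$n_participants, 25L)
  expect_equal(p$legs_per_participant, 2L)
  expect_equal(length(p$time_labels), 3L)
  expect_equal(p$amplification_per_time, c(1, 1.27, 1.17))
  expect_equal(p$rna_input_ng, 1000)
  expect_identical(sim_params(), default_params())
})

test_that("invalid parameters are rejected naming the offending field", {
  expect_error(sim_params(n_participants = 1), "n_participants")
  expect_error(sim_params(amplification_per_time = c(1.1, 1.27, 1.17)),
               "amplification_per_time")
  expect_error(sim_params(amplification_per_time = c(1, -1, 1)),
               "amplification_per_time")
  expect_error(sim_params(fraction_de = 0.5, fraction_tissue_stable = 0.3,
                          fraction_library_stable = 0.3), "fraction")
  expect_error(sim_params(not_a_param = 2), "unknown")
})

test_that("simulation is bit-identical under the same seed", {
  p <- sim_params(n_genes = 40, n_participants = 4)
  a <- simulate_study(p, seed = 7)
  b <- simulate_study(p, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$metadata, b$metadata)
  c <- simulate_study(p, seed = 8)
  expect_false(identical(a$counts, c$counts))
})

test_that("study layout: one count column per participant x leg x time", {
  p <- sim_params(n_genes = 30, n_participants = 5)
  st <- simulate_study(p, seed = 2)
  expect_equal(ncol(st$counts), 5 * 2 * 3)
  expect_identical(colnames(st$counts), st$metadata$sample_id)
  expect_true(all(st$counts >= 0))
  expect_true(all(st$counts == round(st$counts)))
})

test_that("no-effect parameterization yields identically zero truth in all viewpoints", {
  p <- sim_params(n_genes = 50, n_participants = 4,
                  amplification_per_time = c(1, 1, 1),
                  mrna_amplification_per_time = c(1, 1, 1),
                  fraction_de = 0, background_wobble_sd = 0,
                  rna_yield_noise_sd = 0)
  st <- simulate_study(p, seed = 3)
  expect_true(all(st$truth$per_mg_log_fc == 0))
  expect_true(all(abs(st$truth$per_library_log_fc) < 1e-12))
  expect_true(all(st$truth$per_total_rna_log_fc == 0))
})

test_that("truth matrices satisfy the gene-class contracts", {
  p <- sim_params(n_genes = 1000, n_participants = 4)
  st <- simulate_study(p, seed = 5)
  tr <- st$truth
  expect_true(all(tr$per_mg_log_fc[, 1] == 0))
  ts <- tr$gene_class == "tissue_stable"
  expect_true(all(tr$per_mg_log_fc[ts, ] == 0))
  # total-RNA-stable genes track the total-RNA amplification exactly
  rs <- tr$gene_class == "totalrna_stable"
  expect_equal(unname(tr$per_mg_log_fc[rs, 2]),
               rep(log(p$amplification_per_time[2]), sum(rs)))
  expect_true(all(abs(tr$per_total_rna_log_fc[rs, ]) < 1e-12))
  # library-stable genes keep a constant mRNA-pool share: per-mg change equals
  # the pool amplification, so their per-library change is near zero
  lsb <- tr$gene_class == "library_stable"
  expect_equal(unname(tr$per_mg_log_fc[lsb, 2]),
               rep(log(p$mrna_amplification_per_time[2]), sum(lsb)))
  expect_true(max(abs(tr$per_library_log_fc[lsb, ])) < 0.05)
  # when the pool grows, genes with fixed per-mg abundance lose pool share
  expect_true(all(tr$per_library_log_fc[ts, 2] < 0))
})

test_that("expected counts: composition trivia and exact conservation", {
  p <- sim_params(n_genes = 20, n_participants = 3)
  st <- simulate_study(p, seed = 11)
  mu <- expected_counts(p, st$truth, st$metadata)
  L <- st$truth$sample_denominator_truth$library_size
  expect_equal(colSums(mu), setNames(L, colnames(mu)), tolerance = 1e-12)
  # two genes with equal abundance split the library evenly
  tr <- st$truth
  tr$baseline_log_abundance[] <- 1
  tr$participant_intercepts[] <- 0
  tr$per_mg_log_fc[] <- 0
  tr$volume_log_fc[] <- 0
  mu2 <- expected_counts(p, tr, st$metadata)
  expect_equal(unname(mu2[1, ]), unname(L / nrow(mu2)), tolerance = 1e-12)
})

test_that("expected counts match a from-scratch recomputation of the formula", {
  p <- sim_params(n_genes = 10, n_participants = 3)
  st <- simulate_study(p, seed = 13)
  mu <- expected_counts(p, st$truth, st$metadata)
  tr <- st$truth
  for (s in c(1, 5, 18)) {
    pt <- st$metadata$participant[s]
    tt <- as.character(st$metadata$time[s])
    Tg <- exp(tr$baseline_log_abundance + tr$participant_intercepts[, pt] +
                tr$per_mg_log_fc[, tt] +
                tr$volume_log_fc * (st$metadata$condition[s] == "moderate"))
    mu_s <- tr$sample_denominator_truth$library_size[s] * Tg / sum(Tg)
    expect_equal(unname(mu[, s]), unname(mu_s), tolerance = 1e-12)
  }
})

test_that("empirical count means agree with the analytic expectation", {
  p <- sim_params(n_genes = 12, n_participants = 3)
  st <- simulate_study(p, seed = 17)
  mu <- expected_counts(p, st$truth, st$metadata)
  phi <- st$truth$dispersion
  nrep <- 200
  acc <- matrix(0, nrow(mu), ncol(mu))
  for (r in seq_len(nrep)) acc <- acc + resample_counts(st, seed = 4000 + r)$counts
  emp <- acc / nrep
  mcse <- sqrt(sweep(mu^2, 1, phi, `*`) + mu) / sqrt(nrep)
  expect_true(all(abs(emp - mu) < 3 * mcse + 1e-9))
  # over-dispersion: across replicates, variance exceeds the mean for phi > 0
  g <- which.max(mu[, 1])
  draws <- vapply(1:300, function(r) resample_counts(st, seed = 9000 + r)$counts[g, 1],
                  numeric(1))
  expect_gt(stats::var(draws), mean(draws))
})
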