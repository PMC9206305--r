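random_counts <- function(seed, ngene = 50, nsamp = 4, depth = 2000) {
  set.seed(seed)
  lam <- stats::rlnorm(ngene, log(depth / ngene), 1)
  scl <- stats::runif(nsamp, 0.5, 2)
  m <- matrix(stats::rpois(ngene * nsamp, outer(lam, scl)), ngene, nsamp,
              dimnames = list(sprintf("g%03d", 1:ngene), sprintf("s%d", 1:nsamp)))
  m
}

test_that("library sizes are column sums, linear in counts", {
  m <- matrix(c(1L, 2L, 3L, 0L, 4L, 6L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(library_sizes(m)), c(6, 10))
  expect_equal(library_sizes(2L * m), 2 * library_sizes(m))
  r <- random_counts(1)
  expect_equal(unname(library_sizes(r)), unname(apply(r, 2, sum)))
  m[, 1] <- 0L
  expect_error(library_sizes(m), "zero total")
})

test_that("TMM trivia: identical samples and pure depth changes give factor 1", {
  r <- random_counts(2) + 1L
  same <- cbind(s1 = r[, 1], s2 = r[, 1], s3 = r[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3))
  depth <- cbind(s1 = r[, 1], s2 = 3L * r[, 1])
  expect_equal(unname(tmm_factors(depth)), c(1, 1))
  expect_error(tmm_factors(r[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("TMM matches the step-by-step oracle and edgeR on random matrices", {
  for (seed in 1:12) {
    r <- random_counts(seed, ngene = sample(20:50, 1), nsamp = sample(2:6, 1))
    r <- r + matrix(stats::rpois(length(r), 1), nrow(r))   # few zeros
    expect_equal(unname(tmm_factors(r)), oracle_tmm(r), tolerance = 1e-10)
  }
  set.seed(99)
  r <- random_counts(77, ngene = 400, nsamp = 5, depth = 40000) + 1L
  f_edger <- edgeR::calcNormFactors(r, method = "TMM")
  expect_equal(unname(tmm_factors(r)), unname(f_edger), tolerance = 1e-8)
})

test_that("TMM factors have geometric mean one and are scale invariant", {
  r <- random_counts(5, nsamp = 6)
  f <- tmm_factors(r)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  expect_equal(unname(tmm_factors(3L * r)), unname(f), tolerance = 1e-10)
})

test_that("denominators follow the mode contracts", {
  st <- simulate_study(sim_params(n_genes = 30, n_participants = 3), seed = 4)
  al <- validate_design(st$counts, st$metadata)
  f <- tmm_factors(al$counts)
  d_lib <- denominators(al$counts, al$meta, "per_library_size", factors = f)
  expect_equal(d_lib$denominator, unname(library_sizes(al$counts) * f))
  d_rna <- denominators(al$counts, al$meta, "per_total_rna")
  expect_true(all(d_rna$denominator == 1e6))
  d_mg <- denominators(al$counts, al$meta, "per_sample_size")
  expect_equal(d_mg$denominator, al$meta$tissue_mass_mg * 1e6)
  expect_error(denominators(al$counts, al$meta, "per_library_size"), "TMM")
  meta2 <- al$meta; meta2$tissue_mass_mg <- NULL
  expect_error(denominators(al$counts, meta2, "per_sample_size"), "tissue_mass_mg")
})

test_that("cpm divides by the denominator and conserves the zero pattern", {
  st <- simulate_study(sim_params(n_genes = 30, n_participants = 3), seed = 6)
  al <- validate_design(st$counts, st$metadata)
  d <- denominators(al$counts, al$meta, "per_total_rna")
  a <- cpm(al$counts, d)
  expect_equal(unname(a[2, 3]), unname(al$counts[2, 3] / 1e6 * 1e6))
  expect_identical(unname(a == 0), unname(al$counts == 0))
  a2 <- cpm(al$counts, d, million_scale = FALSE)
  expect_equal(unname(a2 * 1e6), unname(a))
  # brute-force elementwise check
  expect_equal(unname(a[, 4]), unname(al$counts[, 4] / d$denominator[4] * 1e6))
})

test_that("log transform: base changes leave t-values and ICC unchanged", {
  st <- simulate_study(sim_params(n_genes = 40, n_participants = 4), seed = 8)
  al <- validate_design(st$counts, st$metadata)
  keep <- robust_filter(al$counts, 10)
  d <- denominators(al$counts, al$meta, "per_sample_size")
  a <- cpm(al$counts[keep, , drop = FALSE], d)
  le <- log_cpm(a)
  l2 <- log_cpm(a, base = 2)
  expect_equal(unname(le[1, 1]), log(unname(a[1, 1])))
  X <- screening_design(al$meta)
  fe <- fit_reml(le[3, ], X, al$meta$participant)
  f2 <- fit_reml(l2[3, ], X, al$meta$participant)
  expect_equal(fe$t_values, f2$t_values, tolerance = 1e-6)
  expect_equal(fe$icc, f2$icc, tolerance = 1e-6)
  az <- a; az[1, 1] <- 0
  expect_error(log_cpm(az), "robust")
})

test_that("a common rescaling of all denominators shifts log-CPM additively only", {
  st <- simulate_study(sim_params(n_genes = 40, n_participants = 4), seed = 9)
  al <- validate_design(st$counts, st$metadata)
  keep <- robust_filter(al$counts, 10)
  d <- denominators(al$counts, al$meta, "per_sample_size")
  d2 <- d; d2$denominator <- d$denominator * 7.5
  a1 <- log_cpm(cpm(al$counts[keep, , drop = FALSE], d))
  a2 <- log_cpm(cpm(al$counts[keep, , drop = FALSE], d2))
  expect_lt(max(abs((a1 - a2) - log(7.5))), 1e-12)
  X <- screening_design(al$meta)
  f1 <- fit_reml(a1[5, ], X, al$meta$participant)
  f2 <- fit_reml(a2[5, ], X, al$meta$participant)
  # the additive shift moves only the intercept; condition t-values and ICC stay
  expect_equal(f1$t_values[-1], f2$t_values[-1], tolerance = 1e-6)
  expect_equal(f1$icc, f2$icc, tolerance = 1e-6)
})
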