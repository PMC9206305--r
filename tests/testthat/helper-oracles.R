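# Independent brute-force oracles, written step-by-step (loops, dense algebra)
# on purpose: they must not share code paths with the package implementation.

# --- TMM: literal per-gene loop implementation -------------------------------

oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05, min_count = 1,
                       ref_sample = NULL) {
  ns <- ncol(counts)
  lib <- numeric(ns)
  for (s in seq_len(ns)) lib[s] <- sum(counts[, s])
  if (is.null(ref_sample)) {
    uq <- numeric(ns)
    for (s in seq_len(ns)) uq[s] <- stats::quantile(counts[, s], 0.75) / lib[s]
    ref <- which.min(abs(uq - mean(uq)))
  } else ref <- ref_sample
  f <- numeric(ns)
  for (s in seq_len(ns)) {
    M <- c(); A <- c(); w <- c()
    for (g in seq_len(nrow(counts))) {
      yo <- counts[g, s]; yr <- counts[g, ref]
      if (yo >= min_count && yr >= min_count) {
        po <- yo / lib[s]; pr <- yr / lib[ref]
        m_g <- log2(po / pr)
        a_g <- (log2(po) + log2(pr)) / 2
        w_g <- 1 / ((lib[s] - yo) / (lib[s] * yo) + (lib[ref] - yr) / (lib[ref] * yr))
        if (is.finite(m_g) && is.finite(a_g) && is.finite(w_g)) {
          M <- c(M, m_g); A <- c(A, a_g); w <- c(w, w_g)
        }
      }
    }
    if (!length(M)) { f[s] <- NA; next }
    if (max(abs(M)) < 1e-6) { f[s] <- 1; next }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      if (rM[i] >= loM && rM[i] <= hiM && rA[i] >= loA && rA[i] <= hiA) {
        num <- num + M[i] * w[i]; den <- den + w[i]
      }
    }
    f[s] <- if (den > 0) 2^(num / den) else NA
  }
  f[is.na(f)] <- 1
  g <- exp(mean(log(f)))
  f / g
}

# --- REML: dense-matrix criterion + zooming grid search ----------------------

oracle_reml_criterion <- function(lambda, y, X, groups) {
  g <- factor(groups)
  Z <- stats::model.matrix(~ 0 + g)
  n <- length(y); p <- ncol(X)
  V <- diag(n) + lambda * Z %*% t(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  s2 <- rss / (n - p)
  as.numeric((n - p) * log(s2) +
    determinant(V, logarithm = TRUE)$modulus +
    determinant(XtViX, logarithm = TRUE)$modulus)
}

oracle_reml_lambda <- function(y, X, groups, lo = 1e-6, hi = 1e4, rounds = 3,
                               npts = 121) {
  for (r in seq_len(rounds)) {
    grid <- exp(seq(log(lo), log(hi), length.out = npts))
    crit <- vapply(grid, function(l) oracle_reml_criterion(l, y, X, groups),
                   numeric(1))
    i <- which.min(crit)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(npts, i + 1)]
  }
  best <- exp((log(lo) + log(hi)) / 2)
  # boundary: compare against lambda ~ 0
  if (oracle_reml_criterion(1e-12, y, X, groups) <= min(crit)) 0 else best
}

# --- Benjamini-Hochberg: literal step-up loop --------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) q[i] <- (m / i) * sorted[i]
  if (m > 1) for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# --- mode-comparison: brute-force enumeration over 27 direction triples ------

oracle_patterns <- function(d1, d2, d3) {
  dirs <- c("up", "down", "ns")
  res <- list()
  for (a in dirs) for (b in dirs) for (cc in dirs) {
    n <- sum(d1 == a & d2 == b & d3 == cc)
    if (n > 0 && !(a == "ns" && b == "ns" && cc == "ns"))
      res[[paste(a, b, cc, sep = "/")]] <- n
  }
  unlist(res)
}

# --- small simulation helpers ------------------------------------------------

make_lmm_instance <- function(seed, n_groups = NULL) {
  set.seed(seed)
  m <- if (is.null(n_groups)) sample(4:8, 1) else n_groups
  ni <- sample(3:7, 1)
  g <- rep(seq_len(m), each = ni)
  n <- length(g)
  X <- cbind(`(Intercept)` = 1, x1 = stats::rnorm(n),
             x2 = rep(c(0, 1), length.out = n))
  sb <- stats::runif(1, 0, 1.5)
  se <- stats::runif(1, 0.3, 1.5)
  y <- drop(X %*% c(1, 0.5, -0.3)) + stats::rnorm(m, 0, sb)[g] + stats::rnorm(n, 0, se)
  list(y = y, X = X, groups = g)
}
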