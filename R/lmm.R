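#' Fixed-effects design for the stability screen
#'
#' Builds the model matrix used when screening transcripts for condition
#' effects: intercept + time dummies (vs the baseline level) and, when the
#' design has two volume conditions, a volume dummy and time x volume
#' interactions. All non-intercept columns are "condition" coefficients for
#' [condition_t_max()].
#'
#' @param meta aligned metadata with factor `time` (baseline first) and
#'   `condition`.
#' @param include_volume include the volume main effect (default TRUE).
#' @param include_interactions include time x volume interactions (default TRUE).
#' @return model matrix with attribute `condition_labels`.
#' @export
screening_design <- function(meta, include_volume = TRUE, include_interactions = TRUE) {
  time <- if (is.factor(meta$time)) droplevels(meta$time) else factor(meta$time)
  cond <- factor(meta$condition)
  has_vol <- include_volume && nlevels(cond) >= 2
  df <- data.frame(time = time, condition = cond)
  form <- if (has_vol && include_interactions) ~ time * condition
          else if (has_vol) ~ time + condition
          else ~ time
  X <- stats::model.matrix(form, df)
  attr(X, "condition_labels") <- setdiff(colnames(X), "(Intercept)")
  X
}

#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y = X beta + u_group + e` with `u_group ~ N(0, sigma_b^2)` and
#' `e ~ N(0, sigma_e^2)` by restricted maximum likelihood. The variance ratio
#' `lambda = sigma_b^2 / sigma_e^2` is profiled by one-dimensional bounded
#' optimization of the REML criterion (on the log scale, relative tolerance
#' below 1e-8), exploiting the closed form of `V^{-1}` for a single grouping
#' factor. A boundary fit `sigma_b^2 = 0` is permitted and flagged.
#'
#' Reported t-values are coefficient / SE with SEs from the REML
#' generalized-least-squares information; no small-sample degrees-of-freedom
#' correction is applied (the values feed a screening threshold, not
#' inference).
#'
#' @param y numeric response vector.
#' @param X fixed-effects design matrix (full column rank).
#' @param groups grouping labels (participant), >= 2 distinct values.
#' @return object of class `trinorm_lmm`: coefficients, standard_errors,
#'   t_values, var_between, var_residual, icc, lambda, boundary, converged,
#'   n_obs, n_groups, design_labels.
#' @examples
#' set.seed(1)
#' g <- rep(1:6, each = 4)
#' y <- rnorm(6, sd = 1)[g] + rnorm(24, sd = 0.5)
#' fit <- fit_reml(y, cbind(`(Intercept)` = 1), g)
#' icc(fit)
#' @export
fit_reml <- function(y, X, groups) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(groups) != n)
    stop("y, X and groups must have matching lengths")
  g <- factor(groups)
  m <- nlevels(g)
  if (m < 2) stop("need >= 2 groups")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  gi <- as.integer(g)
  n_i <- tabulate(gi, m)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  Xg <- rowsum(X, gi)                 # m x p group sums of X
  yg <- rowsum(y, gi)[, 1]            # group sums of y

  crit <- function(loglambda) {
    lam <- exp(loglambda)
    a <- lam / (1 + n_i * lam)
    XtViX <- XtX - crossprod(Xg, Xg * a)
    XtViy <- Xty - crossprod(Xg, yg * a)
    R <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    beta <- backsolve(R, forwardsolve(t(R), XtViy))
    rss <- yty - sum(a * yg^2) - sum(beta * XtViy)
    if (rss <= 0) rss <- .Machine$double.xmin
    s2 <- rss / (n - p)
    (n - p) * log(s2) + sum(log1p(n_i * lam)) + 2 * sum(log(diag(R)))
  }
  # lambda = 0 boundary evaluated explicitly (log-scale search cannot reach it)
  crit0 <- crit(-Inf)
  opt <- stats::optimize(crit, interval = c(-16, 16), tol = 1e-9)
  boundary <- crit0 <= opt$objective || opt$minimum <= -16 + 1e-6
  loglam <- if (boundary) -Inf else opt$minimum
  lam <- exp(loglam)

  a <- if (is.finite(loglam)) lam / (1 + n_i * lam) else rep(0, m)
  XtViX <- XtX - crossprod(Xg, Xg * a)
  XtViy <- Xty - crossprod(Xg, yg * a)
  R <- chol(XtViX)
  beta <- drop(backsolve(R, forwardsolve(t(R), XtViy)))
  rss <- yty - sum(a * yg^2) - sum(beta * XtViy)
  s2 <- max(rss, .Machine$double.xmin) / (n - p)
  vb <- if (boundary) 0 else lam * s2
  cov_beta <- chol2inv(R) * s2
  se <- sqrt(diag(cov_beta))
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("b", seq_len(p))
  dimnames(cov_beta) <- list(labels, labels)
  structure(list(
    coefficients = stats::setNames(beta, labels),
    standard_errors = stats::setNames(se, labels),
    vcov = cov_beta,
    t_values = stats::setNames(beta / se, labels),
    var_between = vb,
    var_residual = s2,
    icc = vb / (vb + s2),
    lambda = if (boundary) 0 else lam,
    boundary = boundary,
    converged = TRUE,
    n_obs = n,
    n_groups = m,
    design_labels = labels
  ), class = "trinorm_lmm")
}

#' Intraclass correlation coefficient of a mixed-model fit
#'
#' Between-participant variance relative to total (between + residual)
#' variance; high ICC means expression is consistent within participants
#' across time, the ranking criterion for stable reference genes.
#'
#' @param fit a [fit_reml()] result.
#' @return proportion in \[0, 1\].
#' @export
icc <- function(fit) {
  if (!inherits(fit, "trinorm_lmm")) stop("icc() expects a trinorm_lmm fit")
  fit$var_between / (fit$var_between + fit$var_residual)
}

#' Maximal absolute condition t-value
#'
#' The screening statistic: the maximum of |t| over the named non-intercept
#' coefficients representing study conditions (time, volume and their
#' interactions).
#'
#' @param fit a [fit_reml()] result.
#' @param condition_labels names of condition coefficients (must exclude the
#'   intercept and be non-empty).
#' @return non-negative scalar.
#' @export
condition_t_max <- function(fit, condition_labels) {
  if (!length(condition_labels)) stop("condition_labels must be non-empty")
  unknown <- setdiff(condition_labels, fit$design_labels)
  if (length(unknown))
    stop("unknown coefficient label(s): ", paste(unknown, collapse = ", "))
  if ("(Intercept)" %in% condition_labels)
    stop("condition_labels must exclude the intercept")
  max(abs(fit$t_values[condition_labels]))
}

#' @export
print.trinorm_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (REML): n = %d, groups = %d\n", x$n_obs, x$n_groups))
  print(data.frame(estimate = x$coefficients, se = x$standard_errors,
                   t = x$t_values))
  cat(sprintf("var_between = %.4g, var_residual = %.4g, ICC = %.3f%s\n",
              x$var_between, x$var_residual, x$icc,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}
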