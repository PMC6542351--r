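# Internal IRLS wrappers around stats::glm.fit that work directly on model
# matrices.  The simulation loops refit thousands of small GLMs, so the
# formula/model-frame machinery of stats::glm() is bypassed; the numerics
# are identical (same C-level IRLS).

fit_glm_matrix <- function(X, y, family, offset = NULL, weights = NULL,
                           epsilon = 1e-12, maxit = 100L) {
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  if (is.null(weights)) weights <- rep(1, n)
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, weights = weights, offset = offset, family = family,
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  if (!fit$converged)
    stop("GLM did not converge within ", maxit, " IRLS iterations")
  dropped <- colnames(X)[is.na(fit$coefficients)]
  if (length(dropped))
    stop("design matrix is rank deficient; dropped column(s): ",
         paste(dropped, collapse = ", "))
  fit$x <- X
  fit$prior_weights <- weights
  fit
}

# Poisson/log with offset, fitted as quasipoisson so non-integer direct
# estimates are accepted without spurious warnings (identical IRLS path).
fit_poisson_offset <- function(X, y, offset, weights = NULL, ...) {
  fit_glm_matrix(X, y, stats::quasipoisson(link = "log"),
                 offset = offset, weights = weights, ...)
}

# Logistic fit with a hard separation check: silent penalization would
# change the estimand, so separation fails loudly.  Separation is flagged
# when the fitted index perfectly discriminates sampled from unsampled
# rows (the MLE diverges) or when a *sampled* row gets a numerically zero
# probability (its inverse-probability weight would be unbounded).  A
# numerically zero probability at an unsampled extreme-covariate row is
# legitimate shrinkage toward certainty-of-non-sampling and carries no
# weight, so it is not an error.
fit_logistic <- function(X, s, eps = 1e-6) {
  fit <- fit_glm_matrix(X, s, stats::binomial(link = "logit"))
  p <- fit$fitted.values
  sampled <- s == 1
  if (any(sampled) && any(!sampled)) {
    if (min(p[sampled]) > max(p[!sampled]))
      stop("separation detected in the sampling model (fitted probabilities ",
           "perfectly discriminate sampled from unsampled municipalities); ",
           "coarsen the covariate specification")
    if (min(p[sampled]) < eps)
      stop("separation detected in the sampling model (a sampled ",
           "municipality has fitted probability below ", eps,
           "); coarsen the covariate specification")
  }
  fit
}

# Model-based coefficient covariance (X'WX)^{-1} at convergence,
# dispersion fixed at 1 (Poisson likelihood).
model_cov <- function(fit) {
  XtWX <- crossprod(fit$x * sqrt(fit$weights))
  V <- solve(XtWX)
  dimnames(V) <- list(colnames(fit$x), colnames(fit$x))
  V
}

# Robust (sandwich) coefficient covariance with prior weights treated as
# known.  For canonical links the score is w_i (y_i - mu_i) x_i.
sandwich_cov <- function(fit) {
  mu <- fit$fitted.values
  U <- fit$x * (fit$prior_weights * (fit$y - mu))
  bread <- solve(crossprod(fit$x * sqrt(fit$weights)))
  V <- bread %*% crossprod(U) %*% bread
  dimnames(V) <- list(colnames(fit$x), colnames(fit$x))
  V
}

# One user seed deterministically spawns independent substreams (multiple
# imputation, bootstrap, simulation replicates, ...), so changing M or B
# does not correlate streams.  All derived seeds stay below 2^31.
derive_seeds <- function(seed, n, stream = 1L) {
  stopifnot(stream >= 1L, stream <= 8L)
  set.seed(as.integer(seed))
  base <- sample.int(2147483646L, 8L)
  set.seed(base[stream])
  sample.int(2147483646L, n)
}
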