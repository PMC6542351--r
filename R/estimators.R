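# The four national size estimators.  Each targets the national
# proportion pi = sum(Y_i) / sum(N_i) via an intercept-only Poisson
# regression with offset log(N_i); the methods differ in how they use
# the municipalities without direct estimates.

# Intercept-only (optionally weighted) Poisson fit with offset log(denom):
# the MLE identity gives exp(beta0) = sum(w y) / sum(w N).  Variance of
# log(pi_hat) is the robust sandwich with weights treated as known:
# sum(w^2 (y - pi N)^2) / (pi sum(w N))^2.
intercept_poisson <- function(y, denom, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  if (sum(w * y) <= 0)
    return(list(log_pi = -Inf, var_log = NA_real_, degenerate = TRUE))
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_poisson_offset(X, y, offset = log(denom), weights = w)
  mu <- fit$fitted.values
  A <- sum(w * mu)
  meat <- sum((w * (y - mu))^2)
  list(log_pi = unname(fit$coefficients[1L]), var_log = meat / A^2,
       degenerate = FALSE)
}

wald_size_estimate <- function(method, ip, table, meta = list()) {
  if (ip$degenerate)
    return(new_size_estimate(method, 0, NA_real_, NA_real_, NA_real_, table,
                             meta = meta, flags = "all_counts_zero"))
  z <- stats::qnorm(0.975)
  se <- sqrt(ip$var_log)
  new_size_estimate(method, exp(ip$log_pi), se,
                    exp(ip$log_pi - z * se), exp(ip$log_pi + z * se),
                    table, meta = meta)
}

#' Complete-case estimator
#'
#' Intercept-only Poisson regression with offset `log(denom)` fit to the
#' sampled municipalities only; consistent only under unconditional
#' exchangeability of sampled and unsampled municipalities.  The robust
#' sandwich variance of the log proportion gives a Wald 95% CI on the log
#' scale, exponentiated.
#'
#' @param table a [municipality_table()].
#' @return a `size_estimate`.
#' @export
estimate_complete_case <- function(table) {
  df <- as.data.frame(table)
  s <- df$sampled == 1L
  if (!any(s)) stop("no sampled municipalities")
  ip <- intercept_poisson(df$count[s], df$denom[s])
  wald_size_estimate("complete_case", ip, df)
}

#' Inverse-probability-of-sampling-weighted (IPSW) estimator
#'
#' Sampled municipalities are weighted by the inverse of their fitted
#' sampling probability (spline-expanded logistic model on the contextual
#' covariates) in the intercept-only Poisson model, so that the sampled
#' subset stands in for the whole country.  Consistent when the sampling
#' model is correctly specified.  CI from the robust (weighted) sandwich
#' variance, weights treated as known.
#'
#' @param table a [municipality_table()].
#' @param spec a [covariate_spec()] for the sampling model.
#' @param sampling_fit optional pre-computed [fit_sampling_model()] result.
#' @return a `size_estimate`.
#' @export
estimate_ipsw <- function(table, spec, sampling_fit = NULL) {
  df <- as.data.frame(table)
  s <- df$sampled == 1L
  if (all(s)) {
    w <- rep(1, sum(s))  # full sampling: no selection to correct
  } else {
    if (is.null(sampling_fit)) sampling_fit <- fit_sampling_model(df, spec)
    w <- unname(compute_weights(sampling_fit, df))
  }
  ip <- intercept_poisson(df$count[s], df$denom[s], w)
  wald_size_estimate("ipsw", ip, df,
                     meta = list(weight_range = range(w)))
}

#' Fit the covariate-conditional outcome model
#'
#' (Optionally weighted) Poisson regression of the direct-estimate count
#' on an intercept plus spline-expanded covariates with offset
#' `log(denom)`, fit over the sampled municipalities; the spline basis is
#' built from all municipalities so predictions extend to unsampled rows.
#' The coefficient covariance is model-based for unweighted fits and
#' robust (sandwich) when IPSW weights are supplied.
#'
#' @param table a [municipality_table()].
#' @param spec a [covariate_spec()].
#' @param weights optional vector of weights, one per sampled
#'   municipality in row order.
#' @return an `outcome_model_fit` with coefficients, covariance, the full
#'   design matrix, and strictly positive predicted counts for all rows.
#' @export
fit_outcome_model <- function(table, spec, weights = NULL) {
  df <- as.data.frame(table)
  s <- df$sampled == 1L
  X <- design_matrix(df, spec)
  if (sum(s) < ncol(X))
    stop("only ", sum(s), " sampled municipalities for ", ncol(X),
         " outcome-model parameters")
  if (!is.null(weights) && length(weights) != sum(s))
    stop("need one weight per sampled municipality")
  fit <- fit_poisson_offset(X[s, , drop = FALSE], df$count[s],
                            offset = log(df$denom[s]), weights = weights)
  beta <- stats::setNames(fit$coefficients, colnames(X))
  cov <- if (is.null(weights)) model_cov(fit) else sandwich_cov(fit)
  pred <- df$denom * exp(drop(X %*% beta))
  structure(list(coefficients = beta, cov = cov,
                 weighted = !is.null(weights), offset_name = "log(denom)",
                 design = X,
                 predictions = stats::setNames(pred, df$municipality_id),
                 spec = spec), class = "outcome_model_fit")
}

#' Draw multiple imputations of the missing counts
#'
#' Proper multiple imputation: coefficient vectors are drawn from the
#' approximate posterior \eqn{MVN(\hat\beta, \hat\Sigma)} of the outcome
#' model, and for each draw the count of every unsampled municipality is
#' drawn from a Poisson distribution with mean
#' \eqn{N_i \exp(\tilde Z_i \beta^{(m)})} (rate capped at 1).  Sampled
#' municipalities keep their observed counts in every imputation.
#'
#' @param fit an [fit_outcome_model()] result (unweighted).
#' @param table the table the fit came from.
#' @param M number of imputations, at least 2.
#' @param seed integer seed; the same seed reproduces the draws exactly.
#' @return list of `M` draws, each with elements `m`, `beta`,
#'   `completed_counts`.
#' @export
draw_imputations <- function(fit, table, M, seed = 1L) {
  stopifnot(M >= 2L)
  df <- as.data.frame(table)
  uns <- df$sampled == 0L
  Sigma <- fit$cov
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (any(ev$values < 0)) {
    if (any(ev$values < -1e-8 * max(abs(ev$values), 1e-300)))
      warning("posterior covariance repaired by clipping negative eigenvalues at 0")
    Sigma <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  }
  set.seed(derive_seeds(seed, 1L, stream = 1L))
  betas <- MASS::mvrnorm(M, fit$coefficients, Sigma)
  lapply(seq_len(M), function(m) {
    yc <- df$count
    if (any(uns)) {
      lam <- df$denom[uns] * exp(drop(fit$design[uns, , drop = FALSE] %*% betas[m, ]))
      lam <- pmin(lam, df$denom[uns])
      yc[uns] <- stats::rpois(sum(uns), lam)
    }
    list(m = m, beta = betas[m, ],
         completed_counts = stats::setNames(yc, df$municipality_id))
  })
}

#' Pool log-scale estimates across imputations by Rubin's rules
#'
#' Point estimate: mean of the per-imputation log proportions.  Total
#' variance \eqn{T = \bar W + (1 + 1/M) B} with within-imputation mean
#' variance \eqn{\bar W} and between-imputation variance \eqn{B}.
#' Degrees of freedom \eqn{\nu = (M-1)(1 + \bar W / ((1+1/M)B))^2};
#' infinite (normal quantile) when \eqn{B = 0}.
#'
#' @param log_estimates numeric vector of per-imputation log proportions.
#' @param within numeric vector of per-imputation variances of the log
#'   proportion.
#' @return list with `point`, `within`, `between`, `total`, `df`, `m`.
#' @export
pool_rubin <- function(log_estimates, within) {
  M <- length(log_estimates)
  stopifnot(M >= 2L, length(within) == M)
  point <- mean(log_estimates)
  Wbar <- mean(within)
  B <- stats::var(log_estimates)
  Tv <- Wbar + (1 + 1 / M) * B
  df <- if (B > 0) (M - 1) * (1 + Wbar / ((1 + 1 / M) * B))^2 else Inf
  list(point = point, within = Wbar, between = B, total = Tv, df = df, m = M)
}

#' Multiple-imputation estimator
#'
#' Fits the unweighted covariate-conditional Poisson outcome model to the
#' sampled municipalities, draws `M` proper imputations of the missing
#' counts, then fits the intercept-only Poisson analysis model (offset
#' `log(denom)`, unweighted: imputation already adjusts for selection) to
#' each completed country.  The per-imputation log proportions and their
#' sandwich variances are pooled by Rubin's rules; the CI uses the t
#' quantile at the Rubin degrees of freedom, exponentiated.
#'
#' @param table a [municipality_table()].
#' @param spec a [covariate_spec()] for the outcome model.
#' @param M number of imputations (default 50).
#' @param seed integer seed.
#' @return a `size_estimate` whose `meta$rubin` holds the pooled
#'   variance components.
#' @export
estimate_mi <- function(table, spec, M = 50L, seed = 1L) {
  df <- as.data.frame(table)
  fit <- fit_outcome_model(df, spec)
  imps <- draw_imputations(fit, df, M, seed)
  per <- vapply(imps, function(im) {
    ip <- intercept_poisson(unname(im$completed_counts), df$denom)
    c(ip$log_pi, ip$var_log)
  }, numeric(2))
  pr <- pool_rubin(per[1L, ], per[2L, ])
  q <- if (is.finite(pr$df)) stats::qt(0.975, pr$df) else stats::qnorm(0.975)
  se <- sqrt(pr$total)
  new_size_estimate("mi", exp(pr$point), se,
                    exp(pr$point - q * se), exp(pr$point + q * se), df,
                    meta = list(M = M, seed = seed, rubin = pr))
}

# One augmented-IPSW point estimate: sampling model -> weights -> weighted
# outcome model on sampled rows -> predictions for all rows ->
# pi_hat = sum(Yhat) / sum(N) (the intercept-only Poisson of Yhat on
# offset log N in closed form).
aipw_point <- function(df, spec, sampling_spec) {
  s <- df$sampled == 1L
  if (!any(s)) stop("no sampled municipalities in this sample")
  if (all(s)) {
    w <- rep(1, sum(s))
  } else {
    sf <- fit_sampling_model(df, sampling_spec)
    w <- unname(compute_weights(sf, df))
  }
  of <- fit_outcome_model(df, spec, weights = w)
  # a predicted count cannot logically exceed the population at risk
  sum(pmin(of$predictions, df$denom)) / sum(df$denom)
}

#' Augmented IPSW (doubly robust) estimator
#'
#' The "regression" augmented estimator: (1) fit the logistic sampling
#' model and form inverse-probability weights; (2) fit the IPSW-weighted
#' Poisson outcome model on the sampled municipalities; (3) predict the
#' count for every municipality; (4) \eqn{\hat\pi = \sum_i \hat Y_i /
#' \sum_i N_i}.  Consistent if either the sampling model or the outcome
#' model is correctly specified.  The SE is the standard deviation of the
#' log proportion over `B` nonparametric bootstrap resamples of the
#' municipalities (rows resampled with replacement, sampling indicators
#' preserved); the CI is `exp(log pi_hat +/- 1.96 SE)`.  Degenerate or
#' non-convergent replicates are discarded and counted in
#' `meta$n_failed`; more than 10% discarded is an error.
#'
#' @param table a [municipality_table()].
#' @param spec a [covariate_spec()] for the outcome model.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param sampling_spec a [covariate_spec()] for the sampling model
#'   (defaults to `spec`).
#' @return a `size_estimate`.
#' @export
estimate_aipw <- function(table, spec, B = 1000L, seed = 1L,
                          sampling_spec = spec) {
  stopifnot(B >= 2L)
  df <- as.data.frame(table)
  lp <- log(aipw_point(df, spec, sampling_spec))
  seeds <- derive_seeds(seed, B, stream = 2L)
  boot <- vapply(seq_len(B), function(b) {
    set.seed(seeds[b])
    idx <- sample.int(nrow(df), replace = TRUE)
    tryCatch(log(aipw_point(df[idx, , drop = FALSE], spec, sampling_spec)),
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(boot))
  if (n_failed > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed (", n_failed,
         " of ", B, ")")
  se <- stats::sd(boot, na.rm = TRUE)
  z <- stats::qnorm(0.975)
  new_size_estimate("aipw", exp(lp), se, exp(lp - z * se), exp(lp + z * se),
                    df, meta = list(B = B, seed = seed, n_failed = n_failed))
}

#' National count implied by a proportion estimate
#'
#' Scales the estimated proportion and its CI endpoints by the national
#' denominator \eqn{\sum_i N_i}.
#'
#' @param estimate a `size_estimate`.
#' @param table the [municipality_table()] supplying the denominators.
#' @return list with `count`, `ci_low`, `ci_high`.
#' @export
national_count <- function(estimate, table) {
  N <- sum(as.data.frame(table)$denom)
  list(count = estimate$pi_hat * N,
       ci_low = estimate$ci_low * N,
       ci_high = estimate$ci_high * N)
}

#' Run all four estimators on one table
#'
#' @param table a [municipality_table()].
#' @param spec [covariate_spec()] for the outcome model.
#' @param M imputations for [estimate_mi()].
#' @param B bootstrap resamples for [estimate_aipw()].
#' @param seed integer seed.
#' @param sampling_spec [covariate_spec()] for the sampling model.
#' @return named list of `size_estimate`s
#'   (`complete_case`, `ipsw`, `mi`, `aipw`).
#' @export
estimate_all <- function(table, spec, M = 50L, B = 1000L, seed = 1L,
                         sampling_spec = spec) {
  list(complete_case = estimate_complete_case(table),
       ipsw = estimate_ipsw(table, sampling_spec),
       mi = estimate_mi(table, spec, M = M, seed = seed),
       aipw = estimate_aipw(table, spec, B = B, seed = seed,
                            sampling_spec = sampling_spec))
}
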