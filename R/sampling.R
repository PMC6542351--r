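# Sampling (selection) model, inverse-probability-of-sampling weights,
# and design diagnostics: positivity and covariate balance.

#' Fit the sampling model
#'
#' Maximum-likelihood logistic regression of the sampling indicator S on
#' an intercept plus spline-expanded contextual covariates, over all
#' municipalities.  Perfect separation and rank deficiency fail loudly
#' rather than returning a silently penalized or reduced fit.
#'
#' @param table a [municipality_table()] containing both sampled and
#'   unsampled municipalities.
#' @param spec a [covariate_spec()].
#' @return a `sampling_fit`: coefficients, per-municipality fitted
#'   sampling probabilities, inverse-probability weights for the sampled
#'   municipalities, and the expanded design column names.
#' @export
fit_sampling_model <- function(table, spec) {
  df <- as.data.frame(table)
  if (!any(df$sampled == 1L) || !any(df$sampled == 0L))
    stop("sampling model needs both sampled and unsampled municipalities")
  X <- design_matrix(df, spec)
  fit <- fit_logistic(X, df$sampled)
  p <- fit$fitted.values
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    fitted_prob = stats::setNames(p, df$municipality_id),
    weights = stats::setNames(1 / p[df$sampled == 1L],
                              df$municipality_id[df$sampled == 1L]),
    converged = TRUE,
    design_columns = colnames(X)), class = "sampling_fit")
}

#' @export
print.sampling_fit <- function(x, ...) {
  cat("Sampling model (logistic) on", length(x$design_columns),
      "design columns\n")
  cat(sprintf("  %d municipalities, %d sampled\n",
              length(x$fitted_prob), length(x$weights)))
  cat(sprintf("  fitted probabilities: %.3f - %.3f\n",
              min(x$fitted_prob), max(x$fitted_prob)))
  cat(sprintf("  weights (sampled): %.2f - %.2f, sum %.1f\n",
              min(x$weights), max(x$weights), sum(x$weights)))
  invisible(x)
}

#' Inverse probability of sampling weights
#'
#' \eqn{W_i = 1 / \hat p_i} for sampled municipalities; unsampled rows
#' carry no weight.  Optional percentile truncation is available but off
#' by default (no truncation is the reference analysis).
#'
#' @param fit a `sampling_fit`.
#' @param table the table the fit was produced from.
#' @param truncate_at optional upper percentile (e.g. 0.99) at which to
#'   cap weights; a warning reports how many were truncated.
#' @return named numeric vector of weights, one per sampled municipality,
#'   in table row order.
#' @export
compute_weights <- function(fit, table, truncate_at = NULL) {
  df <- as.data.frame(table)
  p <- fit$fitted_prob[df$municipality_id[df$sampled == 1L]]
  if (anyNA(p)) stop("sampling fit does not cover all sampled municipalities")
  if (any(p <= 0)) stop("fitted sampling probability of 0 for a sampled municipality")
  w <- 1 / p
  if (!is.null(truncate_at)) {
    cap <- stats::quantile(w, truncate_at, names = FALSE)
    n_cap <- sum(w > cap)
    if (n_cap) warning(n_cap, " weight(s) truncated at the ",
                       100 * truncate_at, "th percentile")
    w <- pmin(w, cap)
  }
  w
}

#' Positivity diagnostic: sampling probability by covariate strata
#'
#' Cross-classifies municipalities by binned covariates (default:
#' tertiles of the first two continuous-looking covariates, mirroring a
#' density-by-poverty stratification) and reports, per stratum, the number
#' of municipalities, the number sampled, and the sampling proportion.
#' Strata that contain municipalities but no sampled ones signal a
#' positivity violation and are listed in the `empty_strata` attribute.
#'
#' @param table a [municipality_table()].
#' @param binning named list mapping covariate names to either an integer
#'   number of quantile bins or an explicit break vector covering the
#'   observed range.  Default: 3 quantile bins for each of the first two
#'   covariates with more than 10 distinct values.
#' @return data frame (class `positivity_table`) with one row per
#'   stratum; attributes `empty_strata` and `binning`.
#' @export
positivity_table <- function(table, binning = NULL) {
  df <- as.data.frame(table)
  covs <- covariate_names(table)
  if (is.null(binning)) {
    cont <- covs[vapply(covs, function(cv) length(unique(df[[cv]])) > 10L,
                        logical(1))]
    if (length(cont) < 1L) stop("no covariates suitable for default binning")
    use <- utils::head(cont, 2L)
    binning <- stats::setNames(as.list(rep(3L, length(use))), use)
  }
  fct <- lapply(names(binning), function(cv) {
    if (!cv %in% names(df)) stop("binning covariate not in table: ", cv)
    v <- df[[cv]]
    b <- binning[[cv]]
    breaks <- if (length(b) == 1L && b == round(b))
      unique(stats::quantile(v, seq(0, 1, length.out = b + 1), names = FALSE))
    else as.numeric(b)
    f <- cut(v, breaks, include.lowest = TRUE)
    if (anyNA(f))
      stop("municipality ", df$municipality_id[which(is.na(f))[1L]],
           " falls in no bin for covariate ", cv)
    factor(paste0(cv, " ", as.character(f)),
           levels = paste0(cv, " ", levels(f)))
  })
  strat <- interaction(fct, sep = " x ", lex.order = TRUE)
  n <- as.vector(table(strat))
  n_sampled <- as.vector(tapply(df$sampled, strat, sum, default = 0L))
  out <- data.frame(stratum = levels(strat), n = n, n_sampled = n_sampled,
                    prop_sampled = ifelse(n > 0, n_sampled / n, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "empty_strata") <- out$stratum[out$n > 0 & out$n_sampled == 0]
  attr(out, "binning") <- binning
  class(out) <- c("positivity_table", "data.frame")
  out
}

#' Covariate balance between all and sampled municipalities
#'
#' For each covariate: the mean among all municipalities, the mean among
#' sampled municipalities, and the standardized difference
#' \eqn{(\bar z_{sampled} - \bar z_{all}) / SD_{pooled}} with
#' \eqn{SD_{pooled} = \sqrt{(s^2_{all} + s^2_{sampled}) / 2}}.  A
#' zero-variance covariate gets an absent (`NA`) standardized difference
#' rather than a propagated `NaN`.
#'
#' @param table a [municipality_table()].
#' @param spec optional [covariate_spec()] restricting the covariates.
#' @return data frame (class `balance_table`) with one row per covariate.
#' @export
balance_table <- function(table, spec = NULL) {
  df <- as.data.frame(table)
  covs <- if (is.null(spec)) covariate_names(table) else spec$covariates
  s <- df$sampled == 1L
  if (!any(s)) stop("no sampled municipalities")
  rows <- lapply(covs, function(cv) {
    v <- df[[cv]]
    m_all <- mean(v)
    m_s <- mean(v[s])
    sdp <- sqrt((stats::var(v) + stats::var(v[s])) / 2)
    data.frame(covariate = cv, mean_all = m_all, mean_sampled = m_s,
               std_diff = if (is.na(sdp) || sdp == 0) NA_real_
                          else (m_s - m_all) / sdp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("balance_table", "data.frame")
  out
}
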