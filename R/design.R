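# Covariate specification and spline-expanded design matrices shared by
# the sampling (logistic) and outcome (Poisson) models.

#' Covariate specification for one key population
#'
#' Names the contextual covariates entering the sampling and outcome
#' models and which of them are expanded with restricted quadratic spline
#' bases.  Per-population covariate sets differ (e.g. border/port presence
#' for female sex workers, universities for MSM/transgender women), so
#' each population carries its own spec.
#'
#' @param population one of `"FSW"`, `"MSM"`, `"TGW"`.
#' @param covariates character vector of covariate column names.
#' @param continuous covariates to expand with splines; by default any
#'   covariate with at least `min_distinct` distinct values.
#' @param n_knots knots per continuous covariate (default 3, at the
#'   5th/50th/95th percentiles).
#' @param min_distinct continuous covariates with fewer distinct values
#'   fall back to a linear term (small-sample stability).
#' @return a `covariate_spec` object.
#' @export
covariate_spec <- function(population = c("FSW", "MSM", "TGW"), covariates,
                           continuous = NULL, n_knots = 3L,
                           min_distinct = 25L) {
  population <- match.arg(population)
  structure(list(population = population,
                 covariates = as.character(covariates),
                 continuous = continuous,
                 n_knots = as.integer(n_knots),
                 min_distinct = as.integer(min_distinct)),
            class = "covariate_spec")
}

#' Spline-expanded design matrix
#'
#' Intercept plus, for each covariate in the covariate spec: a linear
#' column, and
#' for continuous covariates with enough distinct values a restricted
#' quadratic spline basis with knots placed at equally spaced percentiles
#' of the covariate across *all* municipalities (so sampled-row fits and
#' all-row predictions share one basis).
#'
#' @param table a [municipality_table()] or data frame.
#' @param spec a [covariate_spec()].
#' @return numeric matrix with one row per municipality.
#' @export
design_matrix <- function(table, spec) {
  df <- as.data.frame(table)
  miss <- setdiff(spec$covariates, names(df))
  if (length(miss))
    stop("covariates not present in the table: ", paste(miss, collapse = ", "))
  X <- matrix(1, nrow(df), 1L, dimnames = list(NULL, "(Intercept)"))
  for (cv in spec$covariates) {
    v <- as.numeric(df[[cv]])
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
    wanted <- if (is.null(spec$continuous)) TRUE else cv %in% spec$continuous
    if (wanted && length(unique(v)) >= spec$min_distinct) {
      kn <- tryCatch(default_knots(v, spec$n_knots), error = function(e) NULL)
      if (!is.null(kn) && length(kn) >= 2L) {
        B <- restricted_quadratic_basis(v, kn)
        colnames(B) <- paste0(cv, "_", colnames(B))
        X <- cbind(X, B)
      }
    }
  }
  X
}
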