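# Synthetic countries with known ground truth: covariate-driven key
# population counts and covariate-driven (purposive + random) sampling,
# dimensioned like the Dominican Republic (154 municipalities in 31
# provinces, 30 purposively sampled plus 20 randomly sampled).

# Fixed location/scale constants used to standardize covariates inside
# the generative indices.  Being constants (not sample moments), the true
# sampling and outcome models stay exactly linear in the raw covariates.
COV_SCALES <- list(log_density = c(4.5, 1.2),
                   poverty = c(0.35, 0.13),
                   tourism = c(0, 1),
                   hiv_prev = c(0.012, 0.0055))

std_cols <- function(df, nms) {
  vapply(nms, function(nm) {
    sc <- COV_SCALES[[nm]]
    if (is.null(sc)) sc <- c(mean(df[[nm]]), stats::sd(df[[nm]]))
    (df[[nm]] - sc[1]) / sc[2]
  }, numeric(nrow(df)))
}

# Covariates and denominators for n municipalities (uses the current RNG
# state; callers seed).  Shared by the country generator and the
# intercept calibration so both see the same superpopulation.
gen_covariates <- function(n) {
  log_density <- stats::rnorm(n, COV_SCALES$log_density[1], COV_SCALES$log_density[2])
  zd <- (log_density - COV_SCALES$log_density[1]) / COV_SCALES$log_density[2]
  data.frame(
    log_density = log_density,
    poverty = stats::rbeta(n, 0.35 * 12, 0.65 * 12),
    tourism = stats::rbinom(n, 1L, stats::plogis(-1.3 + 0.9 * zd)),
    hiv_prev = stats::rbeta(n, 0.012 * 400, 0.988 * 400),
    denom = pmax(500, round(exp(9.0 + 0.8 * zd + stats::rnorm(n, 0, 0.45)))))
}

# Solve for the fixed outcome intercept such that the superpopulation
# national proportion E[N pi(Z)] / E[N] equals the target, by Monte Carlo
# over a large fixed-seed covariate sample.  The intercept is a scenario
# constant: every replicate country shares one superpopulation, and the
# simulation scores estimators against its proportion.
calibrate_intercept <- function(target, beta, n = 500000L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(20140154L)
  df <- gen_covariates(n)
  eta <- drop(std_cols(df, names(beta)) %*% beta)
  f <- function(c0) sum(df$denom * pmin(exp(c0 + eta), 0.5)) / sum(df$denom) - target
  stats::uniroot(f, c(log(target) - 6, log(target) + 3), tol = 1e-12)$root
}

#' Define a synthetic-country scenario
#'
#' The defaults describe the study conditions the package is built for: a
#' country of 154 municipalities in 31 provinces with 30 purposively and
#' 20 randomly sampled municipalities, an FSW-like national proportion of
#' 3.7%, key population prevalence decreasing with population density and
#' increasing with poverty, and purposive sampling concentrated in dense,
#' touristic, less poor municipalities -- the configuration that makes the
#' crude complete-case estimate understate the national proportion.
#'
#' Selection mechanisms: `"two_stage"` (default) ranks municipalities by
#' a perceived-risk index \eqn{\alpha'\tilde Z + } Gumbel noise and takes
#' the top `n_purposive`, then adds `n_random` uniformly from the rest --
#' a realistic stress test under which a logistic sampling model is only
#' approximately correct.  `"logistic"` draws a single Bernoulli stage
#' with \eqn{P(S=1|Z) = \mathrm{expit}(\alpha_0 + \alpha'\tilde Z)} and
#' \eqn{\alpha_0} calibrated so the expected sample size is
#' `n_purposive + n_random`; under it the fitted logistic sampling model
#' is exactly correctly specified, which is what the simulation study
#' uses for its "sampling model correct" cells.
#'
#' @param k number of municipalities.
#' @param n_provinces number of provinces.
#' @param n_purposive,n_random sampled municipalities per stage.
#' @param target_pi superpopulation national proportion (FSW-like 0.037;
#'   MSM-like 0.012; TGW-like 0.0019).  The outcome intercept is solved
#'   once, at scenario construction, so that the expected
#'   denominator-weighted rate over the covariate superpopulation equals
#'   this value; every replicate country then shares one fixed
#'   data-generating law and the simulation scores estimators against
#'   `pi_star = target_pi`.
#' @param beta named log-rate coefficients on standardized covariates.
#' @param alpha named logit-scale selection coefficients on standardized
#'   covariates.
#' @param selection `"two_stage"` or `"logistic"` (see Details).
#' @param count_model `"poisson"` (default) or `"binomial"` robustness
#'   switch for the true counts.
#' @param misspecification analysis-model misspecification switch used by
#'   [run_scenario()]: `"none"`, `"omit_covariate_in_sampling"`,
#'   `"omit_covariate_in_outcome"`, or `"wrong_functional_form"`.
#' @param key_covariate covariate targeted by the misspecification
#'   switches.
#' @param gumbel_scale noise scale of the perceived-risk index.
#' @return a `kp_scenario` object.
#' @export
scenario <- function(k = 154L, n_provinces = 31L,
                     n_purposive = 30L, n_random = 20L,
                     target_pi = 0.037,
                     beta = c(log_density = -0.55, poverty = 0.45,
                              tourism = 0.25, hiv_prev = 0.15),
                     alpha = c(log_density = 0.80, poverty = -0.50,
                               tourism = 0.50),
                     selection = c("two_stage", "logistic"),
                     count_model = c("poisson", "binomial"),
                     misspecification = c("none",
                                          "omit_covariate_in_sampling",
                                          "omit_covariate_in_outcome",
                                          "wrong_functional_form"),
                     key_covariate = "log_density",
                     gumbel_scale = 1) {
  selection <- match.arg(selection)
  count_model <- match.arg(count_model)
  misspecification <- match.arg(misspecification)
  stopifnot(k >= 4L, n_purposive + n_random <= k,
            target_pi > 0, target_pi < 0.5)
  structure(list(k = as.integer(k), n_provinces = as.integer(n_provinces),
                 n_purposive = as.integer(n_purposive),
                 n_random = as.integer(n_random),
                 target_pi = target_pi, beta = beta, alpha = alpha,
                 beta0 = calibrate_intercept(target_pi, beta),
                 pi_star = target_pi,
                 selection = selection, count_model = count_model,
                 misspecification = misspecification,
                 key_covariate = key_covariate,
                 gumbel_scale = gumbel_scale),
            class = "kp_scenario")
}

#' Generate one synthetic country
#'
#' Covariates: log population density (normal), proportion in poverty and
#' general-population HIV prevalence (beta), tourism presence (Bernoulli
#' with density-linked probability).  Denominators are rounded lognormals
#' scaled to density.  True municipal rates are
#' \eqn{\pi_i = \exp(\beta_0 + \beta'\tilde Z_i)} with the scenario's
#' fixed intercept, capped below 0.5 (a cap binding for more than 5% of
#' municipalities is an error: the scenario is too extreme).  True
#' counts are Poisson (or
#' binomial) draws; selection follows the scenario's mechanism; counts
#' are revealed only where sampled.  Covariate and selection draws happen
#' before outcome draws, so scenarios differing only in `target_pi` (the
#' three key populations sharing one country) share covariates and
#' sampled municipalities under the same seed.
#'
#' @param sc a [scenario()].
#' @param seed integer seed; identical seeds give identical countries.
#' @return a `truth_table`: a [municipality_table()] with hidden columns
#'   `true_count`, `true_pi`, `sampling_stage` and attributes `pi_true`
#'   (the realized \eqn{\sum Y_i / \sum N_i}) and `scenario`.
#' @export
generate_country <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "kp_scenario"))
  set.seed(as.integer(seed))
  k <- sc$k

  province <- sprintf("P%02d", sample(rep_len(seq_len(sc$n_provinces), k)))
  df <- gen_covariates(k)
  denom <- df$denom
  df$denom <- NULL

  # true municipal rates around the scenario's fixed intercept
  eta_out <- drop(std_cols(df, names(sc$beta)) %*% sc$beta)
  pi_i <- exp(sc$beta0 + eta_out)
  if (mean(pi_i > 0.5) > 0.05)
    stop("scenario too extreme: true rate capped at 0.5 for more than 5% of municipalities")
  pi_i <- pmin(pi_i, 0.5)

  # selection before outcome draws (shared across populations per seed)
  eta_s <- drop(std_cols(df, names(sc$alpha)) %*% sc$alpha)
  stage <- rep("none", k)
  if (sc$selection == "two_stage") {
    gumbel <- -log(-log(stats::runif(k))) * sc$gumbel_scale
    purposive <- order(eta_s + gumbel, decreasing = TRUE)[seq_len(sc$n_purposive)]
    stage[purposive] <- "purposive"
    stage[sample(which(stage == "none"), sc$n_random)] <- "random"
  } else {
    n_target <- sc$n_purposive + sc$n_random
    a0 <- stats::uniroot(function(a) sum(stats::plogis(a + eta_s)) - n_target,
                         c(-40, 40))$root
    stage[stats::runif(k) < stats::plogis(a0 + eta_s)] <- "random"
  }
  S <- as.integer(stage != "none")

  Y <- if (sc$count_model == "poisson")
    pmin(stats::rpois(k, denom * pi_i), denom)
  else stats::rbinom(k, denom, pi_i)

  tab <- data.frame(municipality_id = sprintf("M%03d", seq_len(k)),
                    province_id = province, denom = denom, sampled = S,
                    count = ifelse(S == 1L, Y, NA_real_),
                    df,
                    true_count = Y, true_pi = pi_i, sampling_stage = stage,
                    stringsAsFactors = FALSE)
  tab <- municipality_table(tab)
  attr(tab, "pi_true") <- sum(Y) / sum(denom)
  attr(tab, "pi_star") <- sc$pi_star
  attr(tab, "scenario") <- sc
  class(tab) <- unique(c("truth_table", class(tab)))
  tab
}

#' Strip hidden truth columns
#'
#' @param truth a `truth_table` from [generate_country()].
#' @return the analysis-facing [municipality_table()] without ground
#'   truth.
#' @export
analysis_table <- function(truth) {
  df <- as.data.frame(truth)
  municipality_table(df[, setdiff(names(df), HIDDEN_COLUMNS)])
}

#' Default covariate specification for generated countries
#'
#' @param population one of `"FSW"`, `"MSM"`, `"TGW"`.
#' @return a [covariate_spec()] on `log_density`, `poverty`, `tourism`,
#'   `hiv_prev` with splines on the continuous three.
#' @export
default_covariate_spec <- function(population = "FSW") {
  covariate_spec(population,
                 covariates = c("log_density", "poverty", "tourism", "hiv_prev"),
                 continuous = c("log_density", "poverty", "hiv_prev"))
}

#' Packaged DR-like fixture
#'
#' A fixed default scenario: 154 municipalities in 31 provinces, 30
#' purposively and 20 randomly sampled (two-stage mechanism), with an
#' FSW-like national rate near 3.7%, MSM-like near 1.2%, or TGW-like
#' near 0.19%.  The three populations share covariates, denominators and
#' the sampled set for a given seed.
#'
#' @param seed integer seed (default 2014).
#' @param population `"FSW"`, `"MSM"`, or `"TGW"`.
#' @return a `truth_table`.
#' @export
dr_like_fixture <- function(seed = 2014L, population = c("FSW", "MSM", "TGW")) {
  population <- match.arg(population)
  target <- switch(population, FSW = 0.037, MSM = 0.012, TGW = 0.0019)
  generate_country(scenario(target_pi = target), seed)
}

#' Generate cluster indicator points on a linear surface
#'
#' Test input for [interpolate_clusters()]: `n_points` uniform locations
#' on a rectangle with `value = b0 + b1 x + b2 y + noise`.
#'
#' @param surface_coefficients numeric length 3: intercept and the two
#'   slopes.
#' @param n_points number of points, at least 3.
#' @param seed integer seed.
#' @param noise_sd Gaussian noise SD (0 for an exact linear surface).
#' @param xlim,ylim rectangle bounds.
#' @return data frame with columns `x`, `y`, `value`.
#' @export
generate_cluster_fixture <- function(surface_coefficients = c(1, 2, -3),
                                     n_points = 50L, seed = 1L,
                                     noise_sd = 0,
                                     xlim = c(0, 1), ylim = c(0, 1)) {
  stopifnot(n_points >= 3L, length(surface_coefficients) == 3L)
  set.seed(as.integer(seed))
  x <- stats::runif(n_points, xlim[1], xlim[2])
  y <- stats::runif(n_points, ylim[1], ylim[2])
  value <- surface_coefficients[1] + surface_coefficients[2] * x +
    surface_coefficients[3] * y + stats::rnorm(n_points, 0, noise_sd)
  data.frame(x = x, y = y, value = value)
}
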