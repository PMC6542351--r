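# Factorial simulation experiments: replicate countries, estimator
# performance summaries (bias, RMSE, coverage, CI width), and the 2x2
# double-robustness grid.

misspec_covariates <- function(sc, model) {
  covs <- names(sc$beta)
  key <- sc$key_covariate
  switch(sc$misspecification,
         none = covs,
         omit_covariate_in_sampling =
           if (model == "sampling") setdiff(covs, key) else covs,
         omit_covariate_in_outcome =
           if (model == "outcome") setdiff(covs, key) else covs,
         wrong_functional_form =
           if (model == "sampling") replace(covs, covs == key,
                                            paste0(key, "_bin")) else covs)
}

#' Run one simulation scenario
#'
#' Generates `n_reps` independent replicate countries (seeds spawned from
#' one master seed), applies the requested estimators to each, and
#' summarizes per-method performance against each replicate's own true
#' national proportion.  Replicate failures are counted, never silently
#' averaged over; a method failing in more than 10% of replicates is
#' flagged invalid.
#'
#' The AIPW bootstrap CI is the expensive part of a replicate, so it is
#' computed only when `aipw_ci = TRUE`; with `aipw_ci = FALSE` the AIPW
#' point estimate is still computed and its coverage reported as `NA`.
#'
#' @param sc a [scenario()]; its `misspecification` switch determines the
#'   default analysis covariate sets.
#' @param methods subset of `c("cc", "ipsw", "mi", "aipw")`.
#' @param n_reps number of replicates, at least 2.
#' @param seed master seed.
#' @param M imputations per replicate.
#' @param B bootstrap resamples per replicate (when `aipw_ci`).
#' @param aipw_ci compute the AIPW bootstrap CI?
#' @param sampling_covariates,outcome_covariates optional explicit
#'   analysis covariate sets overriding the misspecification switch.
#' @return a `simulation_result` data frame, one row per method, with
#'   columns `method`, `n_reps`, `n_failed`, `valid`, `pi_true`,
#'   `mean_estimate`, `bias`, `relative_bias`, `rmse`, `empirical_se`,
#'   `mean_log_se`, `coverage`, `mean_ci_width`.
#' @export
run_scenario <- function(sc, methods = c("cc", "ipsw", "mi", "aipw"),
                         n_reps = 500L, seed = 1L, M = 20L, B = 200L,
                         aipw_ci = TRUE,
                         sampling_covariates = NULL,
                         outcome_covariates = NULL) {
  stopifnot(inherits(sc, "kp_scenario"), n_reps >= 2L)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(sampling_covariates))
    sampling_covariates <- misspec_covariates(sc, "sampling")
  if (is.null(outcome_covariates))
    outcome_covariates <- misspec_covariates(sc, "outcome")
  cont <- c("log_density", "poverty", "hiv_prev")
  spec_samp <- covariate_spec("FSW", sampling_covariates,
                              continuous = intersect(cont, sampling_covariates))
  spec_out <- covariate_spec("FSW", outcome_covariates,
                             continuous = intersect(cont, outcome_covariates))
  key_bin <- paste0(sc$key_covariate, "_bin")
  need_bin <- key_bin %in% c(sampling_covariates, outcome_covariates)

  seeds <- derive_seeds(seed, n_reps, stream = 3L)
  est <- array(NA_real_, dim = c(n_reps, length(methods), 4L),
               dimnames = list(NULL, methods, c("pi", "lo", "hi", "log_se")))
  pi_real <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    tt <- generate_country(sc, seeds[r])
    df <- as.data.frame(tt)
    if (need_bin)
      df[[key_bin]] <- as.numeric(df[[sc$key_covariate]] >
                                    stats::median(df[[sc$key_covariate]]))
    pi_real[r] <- attr(tt, "pi_true")
    for (meth in methods) {
      res <- tryCatch(switch(meth,
        cc = {
          e <- estimate_complete_case(df)
          c(e$pi_hat, e$ci_low, e$ci_high, e$log_se)
        },
        ipsw = {
          e <- estimate_ipsw(df, spec_samp)
          c(e$pi_hat, e$ci_low, e$ci_high, e$log_se)
        },
        mi = {
          e <- estimate_mi(df, spec_out, M = M, seed = seeds[r])
          c(e$pi_hat, e$ci_low, e$ci_high, e$log_se)
        },
        aipw = {
          if (aipw_ci) {
            e <- estimate_aipw(df, spec_out, B = B, seed = seeds[r],
                               sampling_spec = spec_samp)
            c(e$pi_hat, e$ci_low, e$ci_high, e$log_se)
          } else c(aipw_point(df, spec_out, spec_samp), NA_real_, NA_real_,
                   NA_real_)
        }), error = function(e) rep(NA_real_, 4L))
      est[r, meth, ] <- res
    }
  }

  # Estimators and their variance formulas treat the municipalities as a
  # sample from a superpopulation, so performance is scored against the
  # scenario's fixed superpopulation proportion pi_star; the realized
  # per-country proportion fluctuates around it and its mean is reported.
  pi_true <- sc$pi_star
  rows <- lapply(methods, function(meth) {
    pi_hat <- est[, meth, "pi"]
    ok <- !is.na(pi_hat)
    lo <- est[, meth, "lo"]; hi <- est[, meth, "hi"]
    cover <- ifelse(!is.na(lo) & !is.na(hi),
                    lo <= pi_true & pi_true <= hi, NA)
    bias <- mean(pi_hat[ok]) - pi_true
    data.frame(method = meth, n_reps = n_reps, n_failed = sum(!ok),
               valid = sum(!ok) <= 0.1 * n_reps,
               pi_true = pi_true,
               mean_realized_pi = mean(pi_real[ok]),
               mean_estimate = mean(pi_hat[ok]),
               bias = bias,
               relative_bias = bias / pi_true,
               rmse = sqrt(mean((pi_hat[ok] - pi_true)^2)),
               empirical_se = stats::sd(pi_hat[ok]),
               mean_log_se = mean(est[ok, meth, "log_se"]),
               coverage = if (all(is.na(cover))) NA_real_
                          else mean(cover, na.rm = TRUE),
               mean_ci_width = if (all(is.na(cover))) NA_real_
                               else mean(hi - lo, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- sc
  attr(out, "seed") <- seed
  attr(out, "settings") <- list(M = M, B = B, aipw_ci = aipw_ci,
                                sampling_covariates = sampling_covariates,
                                outcome_covariates = outcome_covariates)
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' Double-robustness grid
#'
#' Runs the 2x2 cross of {sampling model correct, incorrect} x
#' {outcome model correct, incorrect} on one base scenario, where
#' "incorrect" omits the scenario's key covariate from the corresponding
#' analysis model.  The AIPW bootstrap CI is computed only in the cells
#' listed in `ci_cells` (default: the both-correct cell, where coverage
#' is assessed); point-estimate bias is computed everywhere.
#'
#' @param base a [scenario()] with `misspecification = "none"`.
#' @param n_reps replicates per cell.
#' @param seed master seed; each cell gets an independent substream.
#' @param M,B imputations and bootstrap resamples per replicate.
#' @param ci_cells character vector of cell names receiving AIPW CIs.
#' @return a `robustness_grid`: named list of `simulation_result`s with
#'   cells `both_correct`, `sampling_wrong`, `outcome_wrong`,
#'   `both_wrong`.
#' @export
double_robustness_suite <- function(base, n_reps = 500L, seed = 1L,
                                    M = 20L, B = 200L,
                                    ci_cells = "both_correct") {
  stopifnot(inherits(base, "kp_scenario"))
  covs <- names(base$beta)
  red <- setdiff(covs, base$key_covariate)
  if (!length(red))
    stop("base scenario needs a key covariate that can be omitted")
  cells <- list(both_correct = list(s = covs, o = covs),
                sampling_wrong = list(s = red, o = covs),
                outcome_wrong = list(s = covs, o = red),
                both_wrong = list(s = red, o = red))
  seeds <- derive_seeds(seed, length(cells), stream = 4L)
  out <- Map(function(cell, nm, sd) {
    run_scenario(base, n_reps = n_reps, seed = sd, M = M, B = B,
                 aipw_ci = nm %in% ci_cells,
                 sampling_covariates = cell$s, outcome_covariates = cell$o)
  }, cells, names(cells), seeds)
  structure(out, class = "robustness_grid", seed = seed)
}

#' @export
print.robustness_grid <- function(x, ...) {
  cat("Double-robustness grid (", attr(x[[1]], "scenario")$k,
      " municipalities per country)\n\n", sep = "")
  df <- grid_to_df(x)
  print(df[, c("cell", "method", "relative_bias", "coverage",
               "mean_ci_width", "n_failed")], digits = 3, row.names = FALSE)
  invisible(x)
}

grid_to_df <- function(grid) {
  do.call(rbind, Map(function(res, nm) {
    cbind(cell = nm, as.data.frame(res), stringsAsFactors = FALSE)
  }, grid, names(grid)))
}

#' Render a simulation report
#'
#' Writes the full result table as CSV and a markdown summary table
#' (methods as rows: estimate, bias, coverage, CI width) alongside it.
#' Re-rendering from the saved CSV reproduces the markdown byte for byte.
#'
#' @param results a `simulation_result`, `robustness_grid`, or a data
#'   frame previously written by this function.
#' @param path output CSV path; the markdown lands next to it with
#'   extension `.md`.
#' @return invisibly, the markdown lines.
#' @export
render_report <- function(results, path) {
  df <- if (inherits(results, "robustness_grid")) grid_to_df(results)
        else as.data.frame(results)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  num <- vapply(df, is.numeric, logical(1))
  fmt <- df
  fmt[num] <- lapply(df[num], function(v) ifelse(is.na(v), "",
                                                 formatC(signif(v, 4),
                                                         format = "g")))
  fmt[] <- lapply(fmt, as.character)
  header <- paste0("| ", paste(names(fmt), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|")
  body <- apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  md <- c("# Simulation report", "", header, sep, body)
  writeLines(md, sub("\\.[^.]*$", ".md", path))
  invisible(md)
}
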