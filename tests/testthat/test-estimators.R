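test_that("complete-case estimate equals the count ratio", {
  # sampled rows Y = (5, 10, 0), N = (100, 200, 100) -> 15 / 400 = 0.0375,
  # with an unsampled row that must be ignored
  tab <- make_table(denom = c(100, 200, 100, 500), sampled = c(1, 1, 1, 0),
                    count = c(5, 10, 0, NA))
  est <- estimate_complete_case(tab)
  expect_equal(est$pi_hat, 0.0375, tolerance = 1e-10)
  expect_true(est$ci_low < est$pi_hat && est$pi_hat < est$ci_high)
  expect_equal(est$national_count, 0.0375 * 900, tolerance = 1e-8)

  # every Y = 0.01 N, all sampled -> exactly 0.01
  tab <- make_table(denom = c(300, 800, 1200), sampled = c(1, 1, 1),
                    count = c(3, 8, 12))
  expect_equal(estimate_complete_case(tab)$pi_hat, 0.01, tolerance = 1e-12)
})

test_that("IRLS estimates match closed-form ratios and the glm/sandwich oracle", {
  skip_if_not_installed("sandwich")
  for (seed in 1:10) {
    tab <- random_table(40, seed)
    df <- as.data.frame(tab)
    s <- df$sampled == 1

    cc <- estimate_complete_case(tab)
    expect_equal(cc$pi_hat, sum(df$count[s]) / sum(df$denom[s]),
                 tolerance = 1e-10)

    sf <- fit_sampling_model(tab, binary_spec)
    w <- unname(compute_weights(sf, tab))
    ip <- estimate_ipsw(tab, binary_spec, sampling_fit = sf)
    expect_equal(ip$pi_hat,
                 sum(w * df$count[s]) / sum(w * df$denom[s]),
                 tolerance = 1e-10)

    # independent variance oracle: stats::glm + sandwich::vcovHC
    g <- stats::glm(count ~ 1, family = stats::quasipoisson(),
                    offset = log(denom), weights = w, data = df[s, ])
    expect_equal(ip$log_se, sqrt(sandwich::vcovHC(g, type = "HC0")[1, 1]),
                 tolerance = 1e-6)
  }
})

test_that("IPSW with a prescribed two-stratum fit matches the hand-weighted ratio", {
  # weights 2 and 1 (sampling probabilities 0.5 and 1):
  # pi = (2 * 1 + 1 * 3) / (2 * 100 + 1 * 100) = 5 / 300
  tab <- make_table(denom = c(100, 100, 100), sampled = c(1, 0, 1),
                    count = c(1, NA, 3), covs = list(z = c(0, 0, 1)))
  fit <- structure(list(coefficients = c(0, 0),
                        fitted_prob = c(M01 = 0.5, M02 = 0.5, M03 = 1.0),
                        weights = c(M01 = 2, M03 = 1), converged = TRUE,
                        design_columns = c("(Intercept)", "z")),
                   class = "sampling_fit")
  est <- estimate_ipsw(tab, binary_spec, sampling_fit = fit)
  expect_equal(est$pi_hat, 5 / 300, tolerance = 1e-10)
})

test_that("equal sampling probabilities collapse IPSW onto the complete case", {
  tab <- random_table(60, 99)
  spec0 <- covariate_spec("FSW", character(0))
  cc <- estimate_complete_case(tab)
  ip <- estimate_ipsw(tab, spec0)
  expect_equal(ip$pi_hat, cc$pi_hat, tolerance = 1e-12)
})

test_that("outcome model recovers known coefficients and predicts positively", {
  set.seed(123)
  k <- 500
  z1 <- rnorm(k); z2 <- rbinom(k, 1, 0.4)
  denom <- round(runif(k, 500, 3000))
  beta <- c(-3.5, 0.4, -0.3)
  mu <- denom * exp(beta[1] + beta[2] * z1 + beta[3] * z2)
  count <- rpois(k, mu)
  s <- rbinom(k, 1, 0.7)
  tab <- make_table(denom, s, count, covs = list(z1 = z1, z2 = z2))
  spec <- covariate_spec("FSW", c("z1", "z2"), continuous = character(0))
  fit <- fit_outcome_model(tab, spec)
  se <- sqrt(diag(fit$cov))
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
  expect_true(all(fit$predictions > 0))

  # null data: covariate coefficients within 3 SE of zero
  count0 <- rpois(k, denom * exp(-3.5))
  tab0 <- make_table(denom, s, count0, covs = list(z1 = z1, z2 = z2))
  fit0 <- fit_outcome_model(tab0, spec)
  se0 <- sqrt(diag(fit0$cov))
  expect_true(all(abs(fit0$coefficients[-1]) < 3 * se0[-1]))
})

test_that("imputation draws are reproducible and respect a degenerate posterior", {
  tt <- dr_like_fixture(4, "FSW")
  spec <- default_covariate_spec()
  fit <- fit_outcome_model(tt, spec)
  d1 <- draw_imputations(fit, tt, M = 5, seed = 42)
  d2 <- draw_imputations(fit, tt, M = 5, seed = 42)
  expect_identical(d1, d2)
  df <- as.data.frame(tt)
  for (d in d1) {
    expect_true(all(d$completed_counts >= 0))
    expect_equal(unname(d$completed_counts[df$sampled == 1]),
                 df$count[df$sampled == 1])
  }

  fit0 <- fit
  fit0$cov[] <- 0
  d0 <- draw_imputations(fit0, tt, M = 3, seed = 1)
  expect_equal(d0[[1]]$beta, fit$coefficients)
  expect_equal(d0[[2]]$beta, fit$coefficients)
})

test_that("draw means match the lognormal moment formula at large M", {
  tt <- dr_like_fixture(4, "FSW")
  spec <- default_covariate_spec()
  fit <- fit_outcome_model(tt, spec)
  dr <- draw_imputations(fit, tt, M = 2000, seed = 31)
  betas <- t(vapply(dr, `[[`, fit$coefficients, "beta"))
  zi <- fit$design[7, ]
  draws <- exp(drop(betas %*% zi))
  analytic <- exp(sum(zi * fit$coefficients) +
                    0.5 * drop(t(zi) %*% fit$cov %*% zi))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - analytic), 4 * mc_se + 1e-12)
})

test_that("Rubin pooling reproduces hand arithmetic and its invariants", {
  pr <- pool_rubin(c(-3.0, -3.2), c(0.04, 0.04))
  expect_equal(pr$point, -3.1)
  expect_equal(pr$within, 0.04)
  expect_equal(pr$between, 0.02)
  expect_equal(pr$total, 0.04 + 1.5 * 0.02)

  # identical imputations: B = 0, total = within, normal df
  pr0 <- pool_rubin(rep(-3, 4), rep(0.01, 4))
  expect_equal(pr0$between, 0)
  expect_equal(pr0$total, pr0$within)
  expect_true(is.infinite(pr0$df))

  # T >= W always; B invariant to imputation order
  set.seed(5)
  lp <- rnorm(8); wv <- runif(8, 0.01, 0.05)
  pr1 <- pool_rubin(lp, wv)
  pr2 <- pool_rubin(rev(lp), rev(wv))
  expect_gte(pr1$total, pr1$within)
  expect_equal(pr1$between, pr2$between)
  expect_equal(pr1$total, pr2$total)
})

test_that("with everything sampled, MI reduces to the complete case", {
  set.seed(10)
  k <- 40
  denom <- round(runif(k, 500, 2000))
  z <- rnorm(k)
  count <- rpois(k, denom * 0.02)
  tab <- make_table(denom, rep(1, k), count, covs = list(z = z))
  spec <- covariate_spec("FSW", "z", continuous = character(0))
  mi <- estimate_mi(tab, spec, M = 4, seed = 2)
  cc <- estimate_complete_case(tab)
  expect_equal(mi$pi_hat, cc$pi_hat, tolerance = 1e-12)
  expect_equal(mi$meta$rubin$between, 0)
})

test_that("intercept-only models collapse AIPW and IPSW onto the complete case", {
  tab <- random_table(60, 7)
  spec0 <- covariate_spec("FSW", character(0))
  cc <- estimate_complete_case(tab)
  ai <- estimate_aipw(tab, spec0, B = 20, seed = 3)
  expect_equal(ai$pi_hat, cc$pi_hat, tolerance = 1e-12)
})

test_that("AIPW with a saturated binary outcome model equals the stratified estimator", {
  # two strata, each with one sampled and one unsampled municipality;
  # stratum rates 1/100 and 3/100; predicted counts 1, 1, 6, 3 ->
  # pi = 11 / 500 = 0.022
  tab <- make_table(denom = c(100, 100, 200, 100), sampled = c(0, 1, 0, 1),
                    count = c(NA, 1, NA, 3), covs = list(z = c(0, 0, 1, 1)))
  # the point estimator directly: bootstrap resamples of a 4-row table
  # degenerate too often for a CI to be meaningful
  pt <- kpsize:::aipw_point(as.data.frame(tab), binary_spec, binary_spec)
  expect_equal(pt, 11 / 500, tolerance = 1e-10)
})

test_that("scaling all counts scales the deterministic estimators exactly", {
  tab <- random_table(80, 13)
  df <- as.data.frame(tab)
  c_scale <- 0.4
  df2 <- df
  df2$count <- df$count * c_scale
  tab2 <- municipality_table(df2)
  expect_equal(estimate_complete_case(tab2)$pi_hat,
               c_scale * estimate_complete_case(tab)$pi_hat, tolerance = 1e-10)
  expect_equal(estimate_ipsw(tab2, binary_spec)$pi_hat,
               c_scale * estimate_ipsw(tab, binary_spec)$pi_hat,
               tolerance = 1e-10)
  expect_equal(estimate_aipw(tab2, binary_spec, B = 30, seed = 5)$pi_hat,
               c_scale * estimate_aipw(tab, binary_spec, B = 30, seed = 5)$pi_hat,
               tolerance = 1e-9)
})

test_that("full sampling returns the national ratio for every estimator", {
  set.seed(17)
  k <- 50
  denom <- round(runif(k, 500, 2000))
  z <- rbinom(k, 1, 0.5)
  count <- rpois(k, denom * (0.01 + 0.01 * z))
  tab <- make_table(denom, rep(1, k), count, covs = list(z = z))
  truth <- sum(count) / sum(denom)
  expect_equal(estimate_complete_case(tab)$pi_hat, truth, tolerance = 1e-10)
  expect_equal(estimate_ipsw(tab, binary_spec)$pi_hat, truth, tolerance = 1e-10)
  expect_equal(estimate_mi(tab, binary_spec, M = 3, seed = 1)$pi_hat, truth,
               tolerance = 1e-10)
  expect_equal(estimate_aipw(tab, binary_spec, B = 20, seed = 1)$pi_hat,
               truth, tolerance = 1e-9)
})

test_that("national counts scale the proportion and its CI by the denominator total", {
  tab <- make_table(denom = c(400000, 600000), sampled = c(1, 1),
                    count = c(4000, 6000))
  est <- estimate_complete_case(tab)
  nc <- national_count(est, tab)
  expect_equal(nc$count, est$pi_hat * 1e6, tolerance = 1e-12)
  expect_equal(nc$ci_low, est$ci_low * 1e6, tolerance = 1e-12)
  expect_equal(nc$count / 1e6, est$pi_hat, tolerance = 1e-12)
})

test_that("an all-zero sampled count is reported with a degeneracy flag", {
  tab <- make_table(denom = c(100, 100), sampled = c(1, 1), count = c(0, 0))
  est <- estimate_complete_case(tab)
  expect_equal(est$pi_hat, 0)
  expect_true("all_counts_zero" %in% est$flags)
})
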