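test_that("a saturated 2x2 sampling model recovers stratum probabilities exactly", {
  # Z = 1: 8 of 10 sampled; Z = 0: 2 of 10 sampled -> fitted 0.8 and 0.2
  z <- rep(c(1, 0), each = 10)
  s <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  tab <- make_table(denom = rep(1000, 20), sampled = s,
                    count = ifelse(s == 1, 10, NA), covs = list(z = z))
  fit <- fit_sampling_model(tab, binary_spec)
  expect_equal(unname(fit$fitted_prob[z == 1]), rep(0.8, 10), tolerance = 1e-10)
  expect_equal(unname(fit$fitted_prob[z == 0]), rep(0.2, 10), tolerance = 1e-10)
  w <- compute_weights(fit, tab)
  expect_equal(unname(w), c(rep(1.25, 8), rep(5, 2)), tolerance = 1e-9)
  expect_length(w, sum(s))
  expect_true(all(w >= 1))

  # weighted representativeness is exact in the saturated case
  df <- as.data.frame(tab)
  zs <- df$z[df$sampled == 1]
  expect_equal(sum(w * zs) / sum(w), mean(df$z), tolerance = 1e-9)
})

test_that("sampling unrelated to covariates gives a near-flat fit with exact mean calibration", {
  set.seed(77)
  k <- 500
  z <- rnorm(k)
  s <- rbinom(k, 1, 0.3)
  tab <- make_table(denom = rep(1000, k), sampled = s,
                    count = ifelse(s == 1, 10, NA), covs = list(z = z))
  spec <- covariate_spec("FSW", "z", continuous = "z")
  fit <- fit_sampling_model(tab, spec)
  # near-flat: fitted probabilities hug the sampling fraction
  expect_gt(mean(fit$fitted_prob > 0.2 & fit$fitted_prob < 0.4), 0.95)
  expect_lt(sd(fit$fitted_prob), 0.05)
  # logistic score equation with an intercept: sum of fitted = n sampled
  expect_equal(sum(fit$fitted_prob), sum(s), tolerance = 1e-8)
})

test_that("perfect separation fails loudly", {
  z <- rep(c(1, 0), each = 8)
  s <- c(rep(1, 8), rep(0, 8))
  tab <- make_table(denom = rep(1000, 16), sampled = s,
                    count = ifelse(s == 1, 5, NA), covs = list(z = z))
  expect_error(fit_sampling_model(tab, binary_spec), "separation|converge")
})

test_that("positivity table counts strata and flags empty ones", {
  tt <- dr_like_fixture(21, "FSW")
  # single stratum covering everything: proportion 50 / 154
  pt <- positivity_table(tt, binning = list(log_density = range(tt$log_density) + c(-1, 1)))
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$n, 154L)
  expect_equal(pt$prop_sampled, 50 / 154)

  pt <- positivity_table(tt)  # default density x poverty tertiles
  expect_equal(sum(pt$n), 154L)
  expect_equal(sum(pt$n_sampled), 50L)
  expect_true(all(pt$prop_sampled >= 0 & pt$prop_sampled <= 1, na.rm = TRUE))

  # permutation invariance of the counts
  df <- as.data.frame(tt)
  perm <- municipality_table(df[sample(nrow(df)), ])
  pt2 <- positivity_table(perm)
  expect_equal(pt2$n, pt$n)
  expect_equal(pt2$n_sampled, pt$n_sampled)

  # a stratum with municipalities but no sampled ones is listed
  z <- c(0, 0, 0, 1, 1, 1)
  s <- c(0, 0, 0, 1, 1, 0)
  tab <- make_table(denom = rep(100, 6), sampled = s,
                    count = ifelse(s == 1, 1, NA), covs = list(z = z))
  pt <- positivity_table(tab, binning = list(z = c(-0.5, 0.5, 1.5)))
  expect_length(attr(pt, "empty_strata"), 1L)
  expect_match(attr(pt, "empty_strata"), "z")
})

test_that("balance table standardizes differences and handles degenerate covariates", {
  # sampled set equal to the full set: all standardized differences 0
  tab <- make_table(denom = rep(100, 6), sampled = rep(1, 6),
                    count = rep(2, 6), covs = list(z = c(1, 2, 3, 4, 5, 6)))
  bt <- balance_table(tab)
  expect_equal(bt$std_diff, 0)

  # hand case: all = 1..6 (mean 3.5, var 3.5); sampled = 4, 5, 6
  # (mean 5, var 1); pooled SD = sqrt((3.5 + 1) / 2) = 1.5 -> (5 - 3.5) / 1.5 = 1
  s <- c(0, 0, 0, 1, 1, 1)
  tab <- make_table(denom = rep(100, 6), sampled = s,
                    count = ifelse(s == 1, 2, NA),
                    covs = list(z = c(1, 2, 3, 4, 5, 6), flat = rep(2, 6)))
  bt <- balance_table(tab)
  expect_equal(bt$std_diff[bt$covariate == "z"], 1)
  expect_true(is.na(bt$std_diff[bt$covariate == "flat"]))
})

test_that("weight totals estimate the number of municipalities", {
  # consistency check at a larger country: E[sum W] = k; the flexible
  # sampling model carries a few percent of upward finite-sample bias at
  # k = 154 which vanishes as k grows
  sc <- scenario(k = 616L, n_purposive = 120L, n_random = 80L,
                 selection = "logistic")
  spec <- default_covariate_spec()
  tot <- vapply(1:30, function(r) {
    tt <- generate_country(sc, 3000 + r)
    sum(fit_sampling_model(tt, spec)$weights)
  }, numeric(1))
  expect_lt(abs(mean(tot) - 616) / 616, 0.02)
})
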