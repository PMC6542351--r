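# Small fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_table <- function(denom, sampled, count = NULL, covs = list(), ids = NULL) {
  k <- length(denom)
  count <- count %||% rep(NA_real_, k)
  df <- data.frame(
    municipality_id = ids %||% sprintf("M%02d", seq_len(k)),
    province_id = "P01",
    denom = denom,
    sampled = sampled,
    count = ifelse(sampled == 1, count, NA_real_),
    stringsAsFactors = FALSE)
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  municipality_table(df)
}

# random valid table with a binary covariate driving nothing in particular
random_table <- function(k, seed) {
  set.seed(seed)
  denom <- round(runif(k, 200, 5000))
  z <- rbinom(k, 1, 0.5)
  sampled <- integer(k)
  # guarantee sampled and unsampled rows in each covariate class
  sampled[sample(which(z == 1), max(1, floor(sum(z == 1) / 2)))] <- 1L
  sampled[sample(which(z == 0), max(1, floor(sum(z == 0) / 3)))] <- 1L
  count <- ifelse(sampled == 1, round(denom * runif(k, 0.001, 0.2), 2), NA_real_)
  make_table(denom, sampled, count, covs = list(z = z))
}

binary_spec <- covariate_spec("FSW", "z", continuous = character(0))
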