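# Core data model: one row per municipality with denominator population N,
# sampling indicator S, direct-estimate count Y (present iff sampled), and
# contextual covariates Z.

REQUIRED_COLUMNS <- c("municipality_id", "province_id", "denom", "sampled", "count")
HIDDEN_COLUMNS <- c("true_count", "true_pi", "sampling_stage")

#' Construct and validate a municipality table
#'
#' A municipality table holds one row per municipality with the denominator
#' population `denom` (the people who could belong to the key population,
#' e.g. women aged 15--49), a binary sampling indicator `sampled`, the
#' direct-estimate count `count` (present exactly when `sampled == 1`;
#' `NA` otherwise), and numeric contextual covariates with no missing
#' values.  Counts may be non-integer: direct estimates are themselves
#' estimates and every downstream model is fit by quasi-likelihood.
#'
#' Validation is total: each invariant either holds or raises an error
#' naming the offending municipality.  Hidden ground-truth columns
#' (`true_count`, `true_pi`, `sampling_stage`) produced by the synthetic
#' generator are carried along but never treated as covariates.
#'
#' @param data data frame with columns `municipality_id`, `province_id`,
#'   `denom`, `sampled`, `count`, plus covariate columns.
#' @param covariates character vector naming the covariate columns; by
#'   default every column that is neither required nor hidden.
#' @return the validated data frame with class `municipality_table` and a
#'   `covariates` attribute.
#' @export
municipality_table <- function(data, covariates = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_COLUMNS, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  data$municipality_id <- as.character(data$municipality_id)
  data$province_id <- as.character(data$province_id)
  if (!is.numeric(data$denom)) stop("column 'denom' must be numeric")
  if (!is.numeric(data$sampled) && !is.logical(data$sampled))
    stop("column 'sampled' must be a 0/1 indicator")
  data$sampled <- as.integer(data$sampled)
  if (!all(data$sampled %in% c(0L, 1L)))
    stop("column 'sampled' must be a 0/1 indicator")
  data$count <- as.numeric(data$count)

  dup <- unique(data$municipality_id[duplicated(data$municipality_id)])
  if (length(dup))
    stop("duplicate municipality_id: ", paste(dup, collapse = ", "))
  bad <- which(!(data$denom > 0))
  if (length(bad))
    stop("denom must be positive; offending municipality: ",
         data$municipality_id[bad[1L]])

  s <- data$sampled == 1L
  bad <- which(s & is.na(data$count))
  if (length(bad))
    stop("sampled municipality has no direct-estimate count: ",
         data$municipality_id[bad[1L]])
  bad <- which(!s & !is.na(data$count))
  if (length(bad))
    stop("count present for unsampled municipality: ",
         data$municipality_id[bad[1L]],
         " (unsampled counts must be absent; see read_municipality_table)")
  bad <- which(s & (data$count < 0 | data$count > data$denom))
  if (length(bad))
    stop("count outside [0, denom] for municipality: ",
         data$municipality_id[bad[1L]])

  if (is.null(covariates))
    covariates <- setdiff(names(data), c(REQUIRED_COLUMNS, HIDDEN_COLUMNS))
  for (cv in covariates) {
    if (!cv %in% names(data)) stop("covariate column not found: ", cv)
    v <- data[[cv]]
    if (!is.numeric(v)) stop("covariate '", cv, "' must be numeric")
    if (anyNA(v)) stop("covariate '", cv, "' contains missing values")
  }

  structure(data, covariates = covariates,
            class = unique(c("municipality_table", class(data))))
}

covariate_names <- function(table) {
  cv <- attr(table, "covariates")
  if (is.null(cv))
    cv <- setdiff(names(table), c(REQUIRED_COLUMNS, HIDDEN_COLUMNS))
  cv
}

#' Read a municipality table from CSV
#'
#' Expects a UTF-8 CSV with a header row and at least the columns
#' `municipality_id, province_id, denom, sampled, count`.  The count cell
#' must be empty for unsampled municipalities; any value present there is
#' marked absent on read (missingness is the core semantics, so a sentinel
#' number is never interpreted as data).
#'
#' @param path path to the CSV file.
#' @param spec optional [covariate_spec()]; when given, its covariate
#'   columns are checked for presence.
#' @return a validated [municipality_table()].
#' @export
read_municipality_table <- function(path, spec = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(municipality_id = "character",
                                        province_id = "character"))
  miss <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(raw$denom))
    stop("non-numeric denom column in ", path)
  raw$count <- suppressWarnings(as.numeric(raw$count))
  raw$count[raw$sampled == 0] <- NA_real_
  tab <- municipality_table(raw)
  if (!is.null(spec)) {
    miss <- setdiff(spec$covariates, names(tab))
    if (length(miss))
      stop("covariates required by the covariate spec are missing from ", path, ": ",
           paste(miss, collapse = ", "))
  }
  tab
}

#' Write a municipality table to CSV
#'
#' Absent counts are written as empty cells so that
#' `read_municipality_table(write_municipality_table(tab))` round-trips
#' field by field.
#'
#' @param table a [municipality_table()].
#' @param path output CSV path.
#' @export
write_municipality_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

new_size_estimate <- function(method, pi_hat, log_se, ci_low, ci_high,
                              table, meta = list(), flags = character()) {
  df <- as.data.frame(table)
  structure(list(
    method = method,
    pi_hat = pi_hat,
    log_se = log_se,
    ci_low = ci_low,
    ci_high = ci_high,
    national_count = pi_hat * sum(df$denom),
    n_total = nrow(df),
    n_sampled = sum(df$sampled == 1L),
    meta = meta,
    flags = flags), class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("National key population size estimate [%s]\n", x$method))
  cat(sprintf("  proportion: %.4g (95%% CI %.4g, %.4g)\n",
              x$pi_hat, x$ci_low, x$ci_high))
  cat(sprintf("  count:      %.0f of %.0f persons\n",
              x$national_count, x$national_count / max(x$pi_hat, .Machine$double.eps)))
  cat(sprintf("  based on %d of %d municipalities sampled\n",
              x$n_sampled, x$n_total))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.size_estimate <- function(x, ...) {
  settings <- if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1L, logical(1))
    paste(names(x$meta)[keep], unlist(x$meta[keep]), sep = "=", collapse = ";")
  } else ""
  data.frame(method = x$method, pi_hat = x$pi_hat, log_se = x$log_se,
             ci_low = x$ci_low, ci_high = x$ci_high,
             national_count = x$national_count,
             n_total = x$n_total, n_sampled = x$n_sampled,
             settings = settings, stringsAsFactors = FALSE)
}

#' Write size estimates to CSV (with optional JSON metadata sidecar)
#'
#' One row per estimate: method label, national proportion, log-scale SE,
#' 95% CI, implied national count, and a settings string.  Values are
#' written at full double precision.
#'
#' @param results a `size_estimate` or nonempty list of them.
#' @param path output CSV path.
#' @param meta_path optional path for a JSON sidecar holding the full
#'   metadata (settings, seeds, pooled variance components, ...).
#' @export
write_estimates <- function(results, path, meta_path = NULL) {
  if (inherits(results, "size_estimate")) results <- list(results)
  if (!length(results)) stop("empty list of estimates")
  if (!all(vapply(results, inherits, logical(1), "size_estimate")))
    stop("all elements must be size_estimate objects")
  df <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(meta_path))
    jsonlite::write_json(lapply(results, unclass), meta_path,
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Read size estimates back from CSV
#'
#' @param path CSV written by [write_estimates()].
#' @return data frame of estimates.
#' @export
read_estimates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
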