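# Restricted quadratic spline bases for flexible functional forms in the
# sampling and outcome models.

#' Restricted quadratic spline basis
#'
#' For knots \eqn{t_1 < \dots < t_K}, column \eqn{j \in 1..K-1} evaluates
#' \deqn{[(x - t_j)_+^2 - (x - t_K)_+^2] / (t_K - t_1).}
#' Each basis function is zero for \eqn{x \le t_1}, has a continuous first
#' derivative everywhere, and is linear in \eqn{x} beyond the last knot,
#' so fitted curves cannot explode in the tails.  The \eqn{t_K - t_1}
#' normalization keeps columns on the scale of `x` (better GLM
#' conditioning); it is a full-rank linear reparameterization and hence
#' inferentially neutral.
#'
#' @param x numeric vector to expand.
#' @param knots strictly ascending numeric vector, length at least 2.
#' @return numeric matrix with `length(knots) - 1` columns and a `knots`
#'   attribute.
#' @export
restricted_quadratic_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L) stop("at least 2 knots are required")
  if (any(diff(knots) <= 0)) stop("knots must be strictly ascending")
  K <- length(knots)
  tK <- knots[K]
  span <- tK - knots[1L]
  pp2 <- function(u) pmax(u, 0)^2
  B <- vapply(knots[-K], function(tj) (pp2(x - tj) - pp2(x - tK)) / span,
              numeric(length(x)))
  B <- matrix(B, nrow = length(x),
              dimnames = list(NULL, paste0("rqs", seq_len(K - 1L))))
  attr(B, "knots") <- knots
  B
}

#' Default knot placement at equally spaced percentiles
#'
#' Knots sit at `n_knots` equally spaced percentiles between the 5th and
#' 95th (e.g. 5th/50th/95th for three knots), computed with
#' linear-interpolation quantiles, then de-duplicated.
#'
#' @param x numeric vector.
#' @param n_knots integer, at least 2.
#' @return strictly ascending numeric vector of knots.
#' @export
default_knots <- function(x, n_knots = 3L) {
  if (n_knots < 2L) stop("n_knots must be at least 2")
  x <- x[!is.na(x)]
  if (length(unique(x)) < max(n_knots, 2L))
    stop("too few distinct values to place ", n_knots, " knots")
  probs <- seq(0.05, 0.95, length.out = n_knots)
  k <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
  if (length(k) < 2L)
    stop("too few distinct values to place ", n_knots, " knots")
  k
}
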