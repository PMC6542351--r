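# Conversion of geolocated survey-cluster indicator points (e.g. DHS HIV
# prevalence) into municipality-level covariates: piecewise-linear
# interpolation over a Delaunay triangulation of the cluster locations,
# evaluated at the centers of a fine regular grid, restricted to the
# convex hull of the clusters, then averaged within each unit.
# Coordinates are treated as planar.

#' Regular grid specification
#'
#' @param xlim,ylim numeric length-2 ranges of the grid.
#' @param nx,ny number of cells along each axis.
#' @return a `grid_spec` list with cell-center coordinates.
#' @export
grid_spec <- function(xlim, ylim, nx = 100L, ny = 100L) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L,
            xlim[2] > xlim[1], ylim[2] > ylim[1], nx >= 1L, ny >= 1L)
  dx <- (xlim[2] - xlim[1]) / nx
  dy <- (ylim[2] - ylim[1]) / ny
  structure(list(xlim = xlim, ylim = ylim, nx = as.integer(nx),
                 ny = as.integer(ny),
                 x = xlim[1] + dx * (seq_len(nx) - 0.5),
                 y = ylim[1] + dy * (seq_len(ny) - 0.5)),
            class = "grid_spec")
}

# Bowyer-Watson incremental Delaunay triangulation.  Point sets here are
# survey clusters (a few hundred at most), so an O(n^2) incremental build
# is ample.  Returns a matrix of point-index triples.
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("at least 3 points are required")
  rx <- range(x); ry <- range(y)
  sc <- max(rx[2] - rx[1], ry[2] - ry[1])
  if (sc == 0) stop("cluster points are all coincident")
  px <- (x - rx[1]) / sc
  py <- (y - ry[1]) / sc
  if (qr(cbind(px - px[1], py - py[1]))$rank < 2L)
    stop("all cluster points are collinear; interpolation needs at least 3 non-collinear points")

  # enclosing super-triangle, removed at the end
  px <- c(px, -30, 31, 0.5)
  py <- c(py, -1, -1, 60)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3L)

  circum <- function(tri) {
    ax <- px[tri[1]]; ay <- py[tri[1]]
    bx <- px[tri[2]]; by <- py[tri[2]]
    cx <- px[tri[3]]; cy <- py[tri[3]]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- t(apply(tris, 1L, circum))

  for (i in seq_len(n)) {
    inside <- (px[i] - cc[, 1])^2 + (py[i] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    bad <- which(inside)
    if (!length(bad)) next  # numerically degenerate; point skipped
    edges <- do.call(rbind, lapply(bad, function(t) {
      tri <- tris[t, ]
      rbind(sort(tri[c(1, 2)]), sort(tri[c(2, 3)]), sort(tri[c(3, 1)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    cc <- rbind(cc, t(apply(newt, 1L, circum)))
    tris <- rbind(tris, newt)
  }
  keep <- apply(tris <= n, 1L, all)
  tris[keep, , drop = FALSE]
}

#' Interpolate cluster indicator points onto a grid
#'
#' Piecewise-linear (barycentric) interpolation over a Delaunay
#' triangulation of the cluster locations, evaluated at grid-cell centers.
#' Cells whose centers fall strictly outside the convex hull of the
#' clusters carry no value.  Linear interpolation is convexity-preserving
#' (no overshoot) and reproduces linear surfaces exactly.
#'
#' @param points data frame with columns `x`, `y`, `value`; at least 3
#'   non-collinear points.
#' @param grid a [grid_spec()]; defaults to a 100 x 100 grid over the
#'   bounding box of the points.
#' @return a `grid_surface`: list with cell-center coordinate vectors `x`,
#'   `y` and an `nx` by `ny` `value` matrix (`NA` outside the hull).
#' @export
interpolate_clusters <- function(points, grid = NULL) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  if (anyNA(points[, c("x", "y", "value")]))
    stop("cluster points contain missing values")
  if (nrow(points) < 3L) stop("at least 3 cluster points are required")
  if (is.null(grid))
    grid <- grid_spec(range(points$x), range(points$y))

  tris <- delaunay_triangulate(points$x, points$y)
  ctr <- expand.grid(x = grid$x, y = grid$y)  # x varies fastest
  vals <- rep(NA_real_, nrow(ctr))
  tol <- 1e-9
  for (t in seq_len(nrow(tris))) {
    un <- which(is.na(vals))
    if (!length(un)) break
    v <- tris[t, ]
    x1 <- points$x[v[1]]; y1 <- points$y[v[1]]
    x2 <- points$x[v[2]]; y2 <- points$y[v[2]]
    x3 <- points$x[v[3]]; y3 <- points$y[v[3]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < .Machine$double.eps) next
    l1 <- ((y2 - y3) * (ctr$x[un] - x3) + (x3 - x2) * (ctr$y[un] - y3)) / det
    l2 <- ((y3 - y1) * (ctr$x[un] - x3) + (x1 - x3) * (ctr$y[un] - y3)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (any(inside))
      vals[un[inside]] <- l1[inside] * points$value[v[1]] +
        l2[inside] * points$value[v[2]] + l3[inside] * points$value[v[3]]
  }
  structure(list(x = grid$x, y = grid$y, grid = grid,
                 value = matrix(vals, nrow = grid$nx, ncol = grid$ny)),
            class = "grid_surface")
}

#' Flatten a grid surface to one row per cell
#'
#' Cells are enumerated with the x index varying fastest; `value` is `NA`
#' outside the convex hull.  Suitable for a CSV dump of the surface.
#'
#' @param x a `grid_surface`.
#' @param ... unused.
#' @return data frame with columns `x`, `y`, `value`.
#' @export
as.data.frame.grid_surface <- function(x, ...) {
  ctr <- expand.grid(x = x$x, y = x$y)
  ctr$value <- as.vector(x$value)
  ctr
}

#' Average a grid surface within administrative units
#'
#' Cells are enumerated with the x index varying fastest (column-major
#' order of the `value` matrix).  Each unit receives the arithmetic mean
#' of its valued cells.  A unit whose cells all lie outside the convex
#' hull gets the value of the nearest valued cell (by center distance) and
#' is flagged `imputed` so the no-missing-covariates invariant can hold
#' downstream without silently fabricating data.
#'
#' @param surface a `grid_surface` from [interpolate_clusters()].
#' @param units character or factor vector of unit labels, one per grid
#'   cell in cell enumeration order.
#' @return data frame with columns `unit`, `value`, `imputed`, ordered by
#'   unit label (invariant to cell enumeration order).
#' @export
aggregate_to_units <- function(surface, units) {
  stopifnot(inherits(surface, "grid_surface"))
  v <- as.vector(surface$value)
  units <- as.character(units)
  if (length(units) != length(v))
    stop("need one unit label per grid cell (", length(v), " cells)")
  if (all(is.na(v))) stop("no valued cells anywhere on the surface")

  ctr <- expand.grid(x = surface$x, y = surface$y)
  ulev <- sort(unique(units))
  valued <- which(!is.na(v))
  out <- lapply(ulev, function(u) {
    idx <- which(units == u)
    vv <- v[idx]
    if (any(!is.na(vv)))
      return(data.frame(unit = u, value = mean(vv, na.rm = TRUE),
                        imputed = FALSE, stringsAsFactors = FALSE))
    # fallback: nearest valued cell to any cell of this unit
    d2 <- outer(ctr$x[idx], ctr$x[valued], "-")^2 +
      outer(ctr$y[idx], ctr$y[valued], "-")^2
    nearest <- valued[arrayInd(which.min(d2), dim(d2))[2]]
    data.frame(unit = u, value = v[nearest], imputed = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
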