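#' Fit a coverage ellipse to a 2-D point cloud
#'
#' Fits the ellipse centered at the cloud mean, shaped by the sample
#' covariance, with its radius set to the empirical Mahalanobis quantile so
#' that the stated fraction of the points lies inside or on the boundary
#' (for `n` points at level `p`, exactly `ceiling(p * n)` points, barring
#' ties). The same construction serves three displays: tolerance ellipses
#' (training-observation projections), prediction ellipses (held-out
#' projection clouds -- these keep the cloud mean as center, which may be
#' offset from the category barycenter; the offset is the estimation
#' bias), and confidence ellipses (bootstrapped barycenters).
#'
#' Collinear clouds give a degenerate ellipse: it is flagged, the shape is
#' replaced by its rank-1 eigenexpansion with a zero minor axis, and
#' containment is tested with the pseudo-inverse.
#'
#' @param points `n x 2` matrix, `n >= 3`.
#' @param level coverage fraction in (0, 1].
#' @param kind `"tolerance"`, `"prediction"` or `"confidence"` (a label
#'   carried in the result).
#' @param dims length-2 integer label of the dimension pair (metadata).
#' @return an object of class `bada_ellipse`: `center`, `shape` (2 x 2
#'   PSD), `radius2`, `level`, `kind`, `dims`, `degenerate`.
#' @export
fit_ellipse <- function(points, level = 0.95,
                        kind = c("tolerance", "prediction", "confidence"),
                        dims = c(1L, 2L)) {
  kind <- match.arg(kind)
  points <- check_numeric_matrix(points, "points")
  if (ncol(points) != 2) stop_("points must have two columns")
  if (nrow(points) < 3) stop_("need at least 3 points")
  if (level <= 0 || level > 1) stop_("level must be in (0, 1]")
  center <- colMeans(points)
  S <- stats::cov(points)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  degenerate <- ev$values[2] <= max(ev$values[1], 0) * 1e-10
  if (degenerate) {
    ev$values[2] <- 0
    S <- ev$values[1] * tcrossprod(ev$vectors[, 1])
    Sinv <- if (ev$values[1] > 0)
      tcrossprod(ev$vectors[, 1]) / ev$values[1] else matrix(0, 2, 2)
  } else {
    Sinv <- solve(S)
  }
  d2 <- stats::mahalanobis(points, center, Sinv, inverted = TRUE)
  radius2 <- sort(d2)[ceiling(level * nrow(points))]
  structure(list(center = center, shape = S, shape_inv = Sinv,
                 radius2 = radius2, level = level, kind = kind,
                 dims = dims, degenerate = degenerate),
            class = "bada_ellipse")
}

#' @export
print.bada_ellipse <- function(x, ...) {
  cat(sprintf("%s ellipse (level %.3g%s): center (%.4g, %.4g)\n",
              x$kind, x$level, if (x$degenerate) ", degenerate" else "",
              x$center[1], x$center[2]))
  invisible(x)
}

#' Test whether points lie inside (or on) an ellipse
#'
#' @param ellipse a `bada_ellipse`.
#' @param points `n x 2` matrix or length-2 vector.
#' @return logical vector.
#' @export
in_ellipse <- function(ellipse, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  d2 <- stats::mahalanobis(points, ellipse$center, ellipse$shape_inv,
                           inverted = TRUE)
  d2 <= ellipse$radius2 * (1 + 1e-9) + 1e-12
}

#' Boundary points of an ellipse
#'
#' @param ellipse a `bada_ellipse`.
#' @param n number of boundary points.
#' @return an `n x 2` matrix tracing the boundary.
#' @export
ellipse_boundary <- function(ellipse, n = 180) {
  ev <- eigen(ellipse$shape, symmetric = TRUE)
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ax <- sqrt(pmax(ev$values, 0) * ellipse$radius2)
  circ <- cbind(cos(ang) * ax[1], sin(ang) * ax[2])
  sweep(circ %*% t(ev$vectors), 2, ellipse$center, "+")
}

#' Approximate overlap test for two ellipses
#'
#' Two ellipses overlap when some point belongs to both. The test is
#' approximate but conservative in practice: it checks each center against
#' the other ellipse, samples points along the segment joining the
#' centers, and checks each ellipse's boundary points against the other.
#' Non-overlap of two categories' confidence ellipses in at least one
#' dimension pair means the categories are separated in the whole space;
#' overlap in a given pair is inconclusive for that projection (it may be
#' a projection artifact).
#'
#' @param e1,e2 `bada_ellipse` objects on the same dimension pair.
#' @param n_grid points sampled along the center segment and per boundary.
#' @return `TRUE` if an overlap is detected.
#' @export
ellipses_overlap <- function(e1, e2, n_grid = 200) {
  if (any(in_ellipse(e2, e1$center)) || any(in_ellipse(e1, e2$center)))
    return(TRUE)
  t <- seq(0, 1, length.out = n_grid)
  seg <- cbind(e1$center[1] + t * (e2$center[1] - e1$center[1]),
               e1$center[2] + t * (e2$center[2] - e1$center[2]))
  if (any(in_ellipse(e1, seg) & in_ellipse(e2, seg))) return(TRUE)
  if (any(in_ellipse(e2, ellipse_boundary(e1, n_grid)))) return(TRUE)
  if (any(in_ellipse(e1, ellipse_boundary(e2, n_grid)))) return(TRUE)
  FALSE
}

#' Confidence ellipses from bootstrapped barycenters, with separation flags
#'
#' Builds one confidence ellipse per category on a chosen dimension pair
#' from a [bootstrap_barycenters()] array, optionally at a
#' multiplicity-corrected level, and reports for every category pair
#' whether the ellipses are disjoint (`"separated"` -- the categories
#' differ significantly in the whole space if this happens in any
#' dimension pair) or overlap (`"inconclusive"` in this projection).
#'
#' @param boot array from [bootstrap_barycenters()].
#' @param dims length-2 dimension pair.
#' @param alpha overall type I error (default 0.05).
#' @param correction `"none"`, `"bonferroni"` or `"sidak"`.
#' @return list with `ellipses` (named list of `bada_ellipse`), `level`,
#'   and `separation` (data frame of category pairs and status).
#' @export
confidence_ellipses <- function(boot, dims = c(1, 2), alpha = 0.05,
                                correction = c("none", "bonferroni", "sidak")) {
  correction <- match.arg(correction)
  categories <- dimnames(boot)[[2]]
  I <- length(categories)
  if (max(dims) > dim(boot)[3]) stop_("dimension pair exceeds model rank")
  level <- corrected_level(alpha, I, correction)
  ells <- lapply(seq_len(I), function(i)
    fit_ellipse(boot[, i, dims], level = level, kind = "confidence",
                dims = as.integer(dims)))
  names(ells) <- categories
  pairs <- utils::combn(I, 2)
  sep <- data.frame(
    category_1 = categories[pairs[1, ]],
    category_2 = categories[pairs[2, ]],
    status = apply(pairs, 2, function(pr)
      if (ellipses_overlap(ells[[pr[1]]], ells[[pr[2]]]))
        "inconclusive" else "separated"),
    stringsAsFactors = FALSE
  )
  list(ellipses = ells, level = level, separation = sep)
}

# Flat data frame representation for ellipses.csv
ellipse_df <- function(ellipses, categories = names(ellipses)) {
  do.call(rbind, lapply(seq_along(ellipses), function(i) {
    e <- ellipses[[i]]
    data.frame(category = categories[i] %||% as.character(i), kind = e$kind,
               dim_1 = e$dims[1], dim_2 = e$dims[2],
               center_x = e$center[1], center_y = e$center[2],
               cov_xx = e$shape[1, 1], cov_xy = e$shape[1, 2],
               cov_yy = e$shape[2, 2], radius2 = e$radius2,
               level = e$level, degenerate = e$degenerate,
               stringsAsFactors = FALSE)
  }))
}
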