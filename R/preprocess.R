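#' Preprocessing transforms with captured parameters
#'
#' Every data-dependent transform estimates its parameters on the training
#' rows and stores them, so held-out observations can be transformed with
#' training parameters only -- the requirement for unbiased cross-validation.
#' [fit_preprocess()] runs an ordered list of steps and returns the
#' transformed matrix plus the fitted step list; [apply_preprocess()] replays
#' the fitted steps on new rows without touching their statistics.
#'
#' Available steps:
#' \describe{
#'   \item{center}{subtract the column mean (uniform over rows).}
#'   \item{center_mass}{subtract the mass-weighted column mean (used by the
#'     correspondence-analysis variant, where it removes the centroid
#'     profile).}
#'   \item{zscore}{center and divide by the column standard deviation with
#'     the population denominator `N` (consistent with uniform masses
#'     `1/N` in the inertia algebra); errors on constant columns.}
#'   \item{row_sum, row_ss}{rescale each row so its element sum, or sum of
#'     squared elements, equals one.}
#'   \item{profile}{divide each row by its sum (relative frequencies).}
#'   \item{hellinger}{square root of the row relative frequencies; output
#'     rows lie on the unit sphere.}
#'   \item{mfa}{divide each subtable by its first singular value, the
#'     multiple-factor-analysis normalization equalizing the subtables'
#'     leading variance.}
#'   \item{statis}{weight each subtable by the square root of its STATIS
#'     weight, derived from the first eigenvector of the between-subtable
#'     RV-coefficient matrix.}
#' }
#'
#' @param x numeric matrix (training rows).
#' @param steps character vector of step names, executed in order.
#' @param subtables factor of length `ncol(x)` mapping columns to subtables
#'   (required by `mfa` and `statis`).
#' @param masses row masses (required by `center_mass`; default uniform).
#' @return `fit_preprocess`: list with `x` (transformed matrix) and `steps`
#'   (fitted parameter list, one element per step, in execution order).
#' @seealso [center_columns()], [zscore_columns()], [normalize_rows()],
#'   [hellinger_transform()], [mfa_normalize_subtables()], [statis_weights()]
#' @export
fit_preprocess <- function(x, steps, subtables = NULL, masses = NULL) {
  x <- check_numeric_matrix(x)
  fitted <- vector("list", length(steps))
  for (s in seq_along(steps)) {
    st <- steps[[s]]
    res <- switch(st,
      center = {
        mu <- colMeans(x)
        x <- sweep(x, 2, mu, "-")
        list(step = "center", means = mu)
      },
      center_mass = {
        m <- masses %||% rep(1 / nrow(x), nrow(x))
        mw <- m / sum(m)
        mu <- colSums(x * mw)
        x <- sweep(x, 2, mu, "-")
        list(step = "center_mass", means = mu)
      },
      zscore = {
        mu <- colMeans(x)
        sdv <- sqrt(colMeans(sweep(x, 2, mu, "-")^2))
        bad <- which(sdv <= 0 | !is.finite(sdv))
        if (length(bad))
          stop_("zero-variance column: %s",
                colnames(x)[bad[1]] %||% as.character(bad[1]))
        x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
        list(step = "zscore", means = mu, sds = sdv)
      },
      row_sum = {
        x <- .normalize_rows(x, "sum")
        list(step = "row_sum")
      },
      row_ss = {
        x <- .normalize_rows(x, "sum_of_squares")
        list(step = "row_ss")
      },
      profile = {
        x <- .profile_rows(x)
        list(step = "profile")
      },
      hellinger = {
        x <- .hellinger(x)
        list(step = "hellinger")
      },
      mfa = {
        if (is.null(subtables)) stop_("'mfa' step needs a column subtable design")
        sc <- .mfa_scales(x, subtables)
        cf <- (1 / sc)[as.integer(as.factor(subtables))]
        x <- sweep(x, 2, cf, "*")
        list(step = "mfa", scales = sc, col_factor = cf)
      },
      statis = {
        if (is.null(subtables)) stop_("'statis' step needs a column subtable design")
        sw <- statis_weights(x, subtables)
        cf <- sqrt(sw$weights)[as.integer(as.factor(subtables))]
        x <- sweep(x, 2, cf, "*")
        list(step = "statis", weights = sw$weights, rv = sw$rv, col_factor = cf)
      },
      stop_("unknown preprocessing step '%s'", st)
    )
    fitted[[s]] <- res
  }
  list(x = x, steps = fitted)
}

#' @rdname fit_preprocess
#' @param fitted the `steps` element returned by `fit_preprocess`.
#' @param newx numeric matrix of new rows (same `J` columns as the training
#'   matrix).
#' @return `apply_preprocess`: the transformed matrix. Parameterized steps
#'   use the stored training parameters; row-wise steps (`row_sum`,
#'   `row_ss`, `profile`, `hellinger`) are parameter-free and recomputed per
#'   row.
#' @export
apply_preprocess <- function(fitted, newx) {
  newx <- check_numeric_matrix(newx)
  for (st in fitted) {
    newx <- switch(st$step,
      center = ,
      center_mass = sweep(newx, 2, st$means, "-"),
      zscore = sweep(sweep(newx, 2, st$means, "-"), 2, st$sds, "/"),
      row_sum = .normalize_rows(newx, "sum"),
      row_ss = .normalize_rows(newx, "sum_of_squares"),
      profile = .profile_rows(newx),
      hellinger = .hellinger(newx),
      mfa = ,
      statis = sweep(newx, 2, st$col_factor, "*"),
      stop_("unknown fitted step '%s'", st$step)
    )
  }
  newx
}

.normalize_rows <- function(x, mode) {
  if (mode == "sum") {
    s <- rowSums(x)
    bad <- which(abs(s) < .Machine$double.eps * ncol(x))
    if (length(bad)) stop_("row %d has zero sum", bad[1])
  } else {
    s <- sqrt(rowSums(x^2))
    bad <- which(s == 0)
    if (length(bad)) stop_("row %d is all zero", bad[1])
  }
  x / s
}

.profile_rows <- function(x) {
  if (any(x < 0)) stop_("negative entry in count table")
  s <- rowSums(x)
  bad <- which(s <= 0)
  if (length(bad)) stop_("row %d has zero total count", bad[1])
  x / s
}

.hellinger <- function(x) sqrt(.profile_rows(x))

.mfa_scales <- function(x, subtables) {
  vapply(levels(as.factor(subtables)), function(k) {
    xk <- x[, as.factor(subtables) == k, drop = FALSE]
    d1 <- svd(xk, nu = 0, nv = 0)$d[1]
    if (!is.finite(d1) || d1 <= 0) stop_("subtable '%s' is all zero", k)
    d1
  }, numeric(1))
}

# Multiply the columns of each subtable by a per-subtable factor.
.scale_subtables <- function(x, subtables, factors) {
  f <- as.factor(subtables)
  sweep(x, 2, factors[as.integer(f)], "*")
}

#' Center columns at their training means
#'
#' @param x numeric matrix.
#' @return list with `x` (centered matrix) and `params` (the stored means).
#' @examples
#' center_columns(matrix(c(1, 2, 3), 3, 1))$x
#' @export
center_columns <- function(x) {
  f <- fit_preprocess(x, "center")
  list(x = f$x, params = f$steps[[1]])
}

#' Standardize columns with the population denominator
#'
#' Columns are centered and divided by the standard deviation computed with
#' denominator `N` (not `N - 1`), the convention consistent with uniform
#' observation masses `1/N`. A constant column is an error (it names the
#' column).
#'
#' @inheritParams center_columns
#' @return list with `x` and `params` (means and sds).
#' @export
zscore_columns <- function(x) {
  f <- fit_preprocess(x, "zscore")
  list(x = f$x, params = f$steps[[1]])
}

#' Normalize rows to unit sum or unit sum of squares
#'
#' @inheritParams center_columns
#' @param mode `"sum"` or `"sum_of_squares"`.
#' @return the normalized matrix.
#' @examples
#' normalize_rows(matrix(c(3, 4), 1, 2), "sum_of_squares")
#' @export
normalize_rows <- function(x, mode = c("sum", "sum_of_squares")) {
  mode <- match.arg(mode)
  .normalize_rows(check_numeric_matrix(x), mode)
}

#' Hellinger transform of a count table
#'
#' Each row becomes the elementwise square root of its relative-frequency
#' profile, so the squared entries of every output row sum to one (rows lie
#' on the unit sphere). Ordinary Euclidean geometry on the transformed rows
#' is the Hellinger distance between the original profiles.
#'
#' @param x nonnegative matrix with positive row sums.
#' @return the transformed matrix.
#' @export
hellinger_transform <- function(x) .hellinger(check_numeric_matrix(x))

#' Multiple-factor-analysis subtable normalization
#'
#' Divides every element of each subtable by that subtable's first singular
#' value, so all subtables enter the joint analysis with a leading singular
#' value of one and none dominates the first dimension merely through its
#' internal variance.
#'
#' @param x numeric matrix.
#' @param subtables factor of length `ncol(x)`.
#' @return list with `x` (normalized matrix) and `scales` (the first
#'   singular value of each subtable, the divisors).
#' @export
mfa_normalize_subtables <- function(x, subtables) {
  x <- check_numeric_matrix(x)
  if (length(subtables) != ncol(x))
    stop_("subtable design has %d records but matrix has %d columns",
          length(subtables), ncol(x))
  sc <- .mfa_scales(x, subtables)
  list(x = .scale_subtables(x, subtables, 1 / sc), scales = sc)
}

#' STATIS subtable weights from the RV-coefficient matrix
#'
#' Computes the `K x K` matrix of RV coefficients between the subtables'
#' row cross-product matrices (each subtable column-centered first), then
#' derives one weight per subtable from the first eigenvector of that
#' matrix, rescaled to sum to one. Subtables sharing more structure with
#' the others receive larger weights; multiplying each subtable by the
#' square root of its weight implements the STATIS compromise weighting.
#'
#' @param x numeric matrix.
#' @param subtables factor of length `ncol(x)`, at least two subtables.
#' @return list with `weights` (length `K`, nonnegative, summing to one)
#'   and `rv` (the `K x K` RV matrix, unit diagonal).
#' @export
statis_weights <- function(x, subtables) {
  x <- check_numeric_matrix(x)
  f <- as.factor(subtables)
  K <- nlevels(f)
  if (K < 2) stop_("STATIS weighting needs at least two subtables")
  S <- lapply(levels(f), function(k) {
    xk <- scale(x[, f == k, drop = FALSE], center = TRUE, scale = FALSE)
    tcrossprod(xk)
  })
  nrm <- vapply(S, function(s) sqrt(sum(s * s)), numeric(1))
  if (any(nrm == 0))
    stop_("subtable '%s' has zero cross-product", levels(f)[which(nrm == 0)[1]])
  rv <- matrix(1, K, K, dimnames = list(levels(f), levels(f)))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i < j) rv[i, j] <- rv[j, i] <- sum(S[[i]] * S[[j]]) / (nrm[i] * nrm[j])
  }
  ev <- eigen(rv, symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev)  # Perron vector of a positive matrix, fixed sign
  w <- ev / sum(ev)
  names(w) <- levels(f)
  list(weights = w, rv = rv)
}
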