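#' Generalized singular value decomposition under row and column metrics
#'
#' Decomposes a real `I x J` matrix `R` as `R = P diag(delta) t(Q)` subject
#' to the metric constraints `t(P) B P = I` and `t(Q) W Q = I`, where `B`
#' is a positive diagonal row-mass metric and `W` a positive-definite
#' column-weight metric (diagonal given as a vector, or a full symmetric
#' matrix). This is the engine of every analysis variant: principal
#' component analysis of barycenters under masses and weights.
#'
#' The computation forms `B^(1/2) R W^(1/2)` (diagonal square roots, or the
#' symmetric square root for a full `W`), takes an ordinary SVD, and
#' back-transforms the singular vectors. Singular values below
#' `max(I, J) * eps * delta_max` are treated as zero and dropped, so `L` is
#' the numerical rank. Sign indeterminacy is resolved by flipping each pair
#' of singular vectors so that the entry of largest absolute value of the
#' right vector is positive (ties broken at the lowest index), making
#' output reproducible across platforms.
#'
#' @param R numeric matrix, `I x J`.
#' @param b row masses: positive vector of length `I`.
#' @param w column weights: positive vector of length `J`, or a `J x J`
#'   symmetric positive-definite matrix.
#' @param tol optional absolute tolerance for the rank cut; default
#'   `max(I, J) * .Machine$double.eps * max(delta)`.
#' @return an object of class `gsvd` with elements `P` (`I x L`), `Q`
#'   (`J x L`), `delta` (length `L`, positive, nonincreasing),
#'   `eigenvalues` (`delta^2`) and `L`.
#' @examples
#' g <- gsvd(diag(c(3, 1)), c(1, 1), c(1, 1))
#' g$delta
#' @export
gsvd <- function(R, b, w, tol = NULL) {
  R <- check_numeric_matrix(R, "R")
  I <- nrow(R)
  J <- ncol(R)
  b <- as.numeric(b)
  if (length(b) != I) stop_("b must have length %d", I)
  if (any(b <= 0) || any(!is.finite(b))) stop_("row masses must be positive")

  if (is.matrix(w)) {
    if (!all(dim(w) == J)) stop_("W must be %d x %d", J, J)
    if (max(abs(w - t(w))) > 1e-8 * max(abs(w), 1))
      stop_("W must be symmetric")
    ew <- eigen((w + t(w)) / 2, symmetric = TRUE)
    if (any(ew$values <= J * .Machine$double.eps * max(ew$values)))
      stop_("W must be positive definite")
    w_half <- ew$vectors %*% (t(ew$vectors) * sqrt(ew$values))
    w_half_inv <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
    Rt <- (sqrt(b) * R) %*% w_half
  } else {
    if (length(w) != J) stop_("w must have length %d", J)
    if (any(w <= 0) || any(!is.finite(w))) stop_("column weights must be positive")
    Rt <- sweep(sqrt(b) * R, 2, sqrt(w), "*")
    w_half_inv <- NULL
  }

  sv <- svd(Rt)
  dmax <- if (length(sv$d)) sv$d[1] else 0
  tol <- tol %||% (max(I, J) * .Machine$double.eps * dmax)
  L <- sum(sv$d > tol)
  P <- sv$u[, seq_len(L), drop = FALSE] / sqrt(b)
  if (is.null(w_half_inv)) {
    Q <- sv$v[, seq_len(L), drop = FALSE] / sqrt(w)
  } else {
    Q <- w_half_inv %*% sv$v[, seq_len(L), drop = FALSE]
  }
  delta <- sv$d[seq_len(L)]

  # deterministic sign: largest |entry| of each right vector made positive
  for (l in seq_len(L)) {
    j <- which.max(abs(Q[, l]))
    if (Q[j, l] < 0) {
      Q[, l] <- -Q[, l]
      P[, l] <- -P[, l]
    }
  }
  rownames(P) <- rownames(R)
  rownames(Q) <- colnames(R)
  structure(list(P = P, Q = Q, delta = delta, eigenvalues = delta^2, L = L),
            class = "gsvd")
}

#' @export
print.gsvd <- function(x, ...) {
  cat(sprintf("gsvd: rank %d, singular values %s\n", x$L,
              paste(signif(x$delta, 4), collapse = ", ")))
  invisible(x)
}

#' Generalized Euclidean squared distance
#'
#' `d_W^2(x, y) = t(x - y) W (x - y)`, the squared distance induced by the
#' column-weight metric; zero iff `x == y` for positive-definite `W`.
#'
#' @param x,y numeric vectors of equal length.
#' @param w positive vector (diagonal metric) or symmetric matrix.
#' @return a nonnegative scalar.
#' @examples
#' generalized_distance(c(1, 0), c(0, 0), c(2, 1))  # 2
#' @export
generalized_distance <- function(x, y, w) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop_("dimension mismatch: %d vs %d",
                                    length(x), length(y))
  d <- x - y
  if (is.matrix(w)) {
    if (!all(dim(w) == length(x))) stop_("W has wrong dimension")
    as.numeric(d %*% w %*% d)
  } else {
    if (length(w) != length(x)) stop_("w has wrong length")
    sum(w * d^2)
  }
}
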