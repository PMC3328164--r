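#' Partial (per-subtable) factor scores
#'
#' The multi-table step: each subtable projects the barycenters (or the
#' observations) onto the common factor space with only its own columns,
#' scaled by the number of subtables:
#' `F_k = K * R_k W_k Q_k`. These partial projections are barycentric --
#' their plain average over the `K` subtables recovers the whole-table
#' factor scores exactly -- so each `F_k` shows how one subject (or ROI)
#' "sees" the category configuration.
#'
#' At the category level the barycenter slice `R_k` is used, so the output
#' is `I x L` per subtable and the averaging identity holds; observation
#' level partial scores (`X_k` slices) are available with
#' `level = "observation"`.
#'
#' For a full (non-diagonal) weight matrix the slice takes the
#' corresponding rows of `W`, which preserves the averaging identity.
#'
#' @param model a fitted `bada` model.
#' @param level `"category"` or `"observation"`.
#' @return an object of class `bada_partial`: list with `scores` (named
#'   list of `I x L` -- or `N x L` -- matrices, one per subtable), `level`
#'   and `K`.
#' @export
partial_scores <- function(model, level = c("category", "observation")) {
  stopifnot(inherits(model, "bada"))
  level <- match.arg(level)
  f <- model$col_subtables
  if (is.null(f)) stop_("model has no column subtable design")
  K <- nlevels(f)
  base <- if (level == "category") model$R else model$Xp
  Q <- model$decomp$Q
  w <- model$w
  scores <- lapply(levels(f), function(k) {
    idx <- which(f == k)
    WQk <- if (is.matrix(w)) w[idx, , drop = FALSE] %*% Q
           else Q[idx, , drop = FALSE] * w[idx]
    K * base[, idx, drop = FALSE] %*% WQk
  })
  names(scores) <- levels(f)
  structure(list(scores = scores, level = level, K = K),
            class = "bada_partial")
}

#' @export
print.bada_partial <- function(x, ...) {
  cat(sprintf("partial %s factor scores for %d subtables\n", x$level, x$K))
  invisible(x)
}

#' Project a supplementary row through one subtable
#'
#' Projects a row observed on the columns of subtable `k` only, using that
#' subtable's slice of the weights and right singular vectors, scaled by
#' `K`: `f = K * x W_k Q_k`. The row must already be on the preprocessed
#' scale of the model's subtable `k` (partial projections compose with
#' row-wise preprocessing only at the level of the full row, so the caller
#' transforms supplementary data with the stored parameters first).
#'
#' @param model a fitted `bada` model.
#' @param x vector of length `J_k` or an `n x J_k` matrix, preprocessed.
#' @param subtable the subtable label.
#' @return an `n x L` matrix of partial factor scores.
#' @export
project_supplementary_partial <- function(model, x, subtable) {
  stopifnot(inherits(model, "bada"))
  f <- model$col_subtables
  if (!(subtable %in% levels(f)))
    stop_("unknown subtable '%s'", subtable)
  idx <- which(f == subtable)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- check_numeric_matrix(x)
  if (ncol(x) != length(idx))
    stop_("x has %d columns but subtable '%s' has %d", ncol(x), subtable,
          length(idx))
  Q <- model$decomp$Q
  w <- model$w
  WQk <- if (is.matrix(w)) w[idx, , drop = FALSE] %*% Q
         else Q[idx, , drop = FALSE] * w[idx]
  nlevels(f) * x %*% WQk
}

#' Partial inertias: each subtable's additive share of every dimension
#'
#' The contribution of subtable `k` to dimension `l` is the sum, over its
#' columns, of the weighted squared variable factor scores
#' (`sum_j w_j g_{j,l}^2` for a diagonal metric). Summed over subtables
#' these recover the dimension's eigenvalue exactly, so the normalized
#' values (divided by the eigenvalue) are scale-free contributions summing
#' to one per dimension -- the quantity used to find which subject or ROI
#' carries the discrimination.
#'
#' @param model a fitted `bada` model.
#' @return list with `inertia` (`K x L` matrix), `contributions`
#'   (`inertia` normalized per dimension) and `eigenvalues`.
#' @export
partial_inertia <- function(model) {
  stopifnot(inherits(model, "bada"))
  f <- model$col_subtables
  if (is.null(f)) stop_("model has no column subtable design")
  G <- model$G
  w <- model$w
  contrib_col <- if (is.matrix(w)) G * (w %*% G) else G * (G * w)
  inertia <- rowsum(contrib_col, as.integer(f))
  ev <- model$decomp$eigenvalues
  contributions <- sweep(inertia, 2, ev, "/")
  dimnames(inertia) <- list(levels(f), colnames(G))
  dimnames(contributions) <- dimnames(inertia)
  list(inertia = inertia, contributions = contributions, eigenvalues = ev)
}
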