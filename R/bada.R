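#' Category barycenters
#'
#' The barycenter of a category is the mass-weighted mean of its rows, with
#' the masses rescaled to sum to one within the category. With uniform
#' masses this is the ordinary category mean.
#'
#' @param x numeric matrix of observations.
#' @param categories category label per row.
#' @param masses optional nonnegative row masses; default uniform.
#' @return an `I x J` matrix, one row per category (level order).
#' @examples
#' compute_barycenters(rbind(c(1, 2), c(3, 4), c(5, 6)), c("A", "A", "B"))
#' @export
compute_barycenters <- function(x, categories, masses = NULL) {
  x <- check_numeric_matrix(x)
  categories <- as.factor(categories)
  if (length(categories) != nrow(x))
    stop_("categories has %d records but matrix has %d rows",
          length(categories), nrow(x))
  masses <- masses %||% rep(1 / nrow(x), nrow(x))
  tot <- tapply(masses, categories, sum)
  if (anyNA(tot) || any(tot <= 0))
    stop_("category '%s' has zero total mass",
          levels(categories)[which(is.na(tot) | tot <= 0)[1]])
  R <- matrix(0, nlevels(categories), ncol(x),
              dimnames = list(levels(categories), colnames(x)))
  for (i in seq_len(nlevels(categories))) {
    sel <- categories == levels(categories)[i]
    R[i, ] <- colSums(x[sel, , drop = FALSE] * masses[sel]) / tot[i]
  }
  R
}

#' Fit a barycentric discriminant model
#'
#' Runs the chosen preprocessing, builds the variant-specific category
#' masses `B` and column weights `W`, computes the matrix of category
#' barycenters `R`, and decomposes it with [gsvd()]. The result carries the
#' category factor scores `F = P diag(delta)`, the variable factor scores
#' (loadings) `G = Q diag(delta)`, and the observation factor scores
#' `H = X W Q`, whose category-wise mass-weighted means recover `F`
#' exactly (the barycentric property).
#'
#' Variants:
#' \describe{
#'   \item{plain}{general numeric data. Default preprocessing is column
#'     centering; any step list accepted by [fit_preprocess()] may be
#'     supplied instead (e.g. `c("center", "mfa", "row_ss")`, the
#'     multi-subject imaging pipeline). Masses and weights are taken from
#'     the table.}
#'   \item{dica}{discriminant correspondence analysis for count data. Rows
#'     are turned into relative-frequency profiles and centered at the
#'     mass-weighted centroid profile; row masses are the row totals over
#'     the grand total (so category masses are the category totals over the
#'     grand total) and column weights are the inverse column relative
#'     frequencies -- the chi-square metric. Category factor scores equal
#'     the row scores of a correspondence analysis of the aggregated
#'     category-by-variable table.}
#'   \item{hellinger}{count data on the sphere: rows become square roots of
#'     relative frequencies, then are centered; masses and weights are
#'     uniform.}
#'   \item{classical}{classical discriminant-analysis metric: after
#'     preprocessing, `W` is the (pseudo-)inverse of the mass-weighted
#'     within-category covariance matrix. When that matrix is singular or
#'     badly conditioned a ridge `ridge * mean(diag(S_within))` is added
#'     before inversion; the condition number is reported in the model.}
#' }
#'
#' @param table a [discriminant_table()].
#' @param variant one of `"plain"`, `"dica"`, `"hellinger"`, `"classical"`.
#' @param steps preprocessing step list for the `plain` and `classical`
#'   variants (default `"center"`); ignored by `dica`/`hellinger`, whose
#'   transform is fixed.
#' @param n_components number of dimensions used for classification
#'   distances; default all `L` nonzero dimensions.
#' @param ridge relative ridge for the `classical` within-covariance
#'   inverse (default `1e-8`, applied only when near-singular).
#' @return an object of class `bada`.
#' @examples
#' sp <- sim_spec(I = 3, n_blocks = 2, scans_per_block = 5, K = 2,
#'                J_k = c(4, 3), effect_size = 2, seed = 1)
#' fit <- bada(simulate_scans(sp)$table)
#' fit$decomp$delta
#' @export
bada <- function(table, variant = c("plain", "dica", "hellinger", "classical"),
                 steps = NULL, n_components = NULL, ridge = 1e-8) {
  stopifnot(inherits(table, "discriminant_table"))
  variant <- match.arg(variant)
  X <- table$data
  cats <- table$row_categories
  m <- table$row_masses
  w <- table$col_weights
  cond_within <- NULL

  if (variant == "dica") {
    if (any(X < 0)) stop_("dica requires nonnegative counts")
    m <- rowSums(X) / sum(X)
    colfreq <- colSums(X) / sum(X)
    zero <- which(colfreq <= 0)
    if (length(zero)) stop_("column %d has zero total frequency", zero[1])
    w <- 1 / colfreq
    pp <- fit_preprocess(X, c("profile", "center_mass"), masses = m)
  } else if (variant == "hellinger") {
    m <- rep(1 / nrow(X), nrow(X))
    w <- rep(1 / ncol(X), ncol(X))
    pp <- fit_preprocess(X, c("hellinger", "center"))
  } else {
    pp <- fit_preprocess(X, steps %||% "center",
                         subtables = table$col_subtables, masses = m)
  }
  Xp <- pp$x

  b <- as.numeric(tapply(m, cats, sum))
  if (any(b <= 0)) stop_("category '%s' has zero total mass",
                         levels(cats)[which(b <= 0)[1]])
  R <- compute_barycenters(Xp, cats, m)

  if (variant == "classical") {
    Sw <- matrix(0, ncol(Xp), ncol(Xp))
    mw <- m / sum(m)
    for (i in seq_len(nlevels(cats))) {
      sel <- cats == levels(cats)[i]
      D <- sweep(Xp[sel, , drop = FALSE], 2, R[i, ], "-")
      Sw <- Sw + crossprod(D * sqrt(mw[sel]))
    }
    es <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE, only.values = TRUE)$values
    cond_within <- max(es) / max(min(es), .Machine$double.eps * max(es))
    if (min(es) <= ncol(Xp) * .Machine$double.eps * max(es)) {
      Sw <- Sw + diag(ridge * mean(diag(Sw)), ncol(Sw))
      w <- MASS::ginv(Sw)
    } else {
      w <- solve(Sw)
    }
    w <- (w + t(w)) / 2
  }

  dec <- gsvd(R, b, w)
  if (!is.null(n_components)) {
    n_components <- min(n_components, dec$L)
  }
  F <- dec$P %*% diag(dec$delta, dec$L)
  G <- dec$Q %*% diag(dec$delta, dec$L)
  WQ <- weight_times(w, dec$Q)
  H <- Xp %*% WQ
  rownames(F) <- levels(cats)
  rownames(G) <- colnames(X)
  if (dec$L > 0)
    colnames(F) <- colnames(G) <- colnames(H) <- paste0("dim", seq_len(dec$L))

  structure(list(
    variant = variant,
    preprocess = pp$steps,
    Xp = Xp,
    R = R,
    b = b,
    w = w,
    WQ = WQ,
    decomp = dec,
    F = F,
    G = G,
    H = H,
    m = m,
    categories = levels(cats),
    row_categories = cats,
    row_blocks = table$row_blocks,
    col_subtables = table$col_subtables,
    n_components = n_components,
    within_cov_condition = cond_within
  ), class = "bada")
}

#' @export
print.bada <- function(x, ...) {
  cat(sprintf("bada fit (%s): %d categories, %d variables, %d dimensions\n",
              x$variant, length(x$categories), nrow(x$G), x$decomp$L))
  ev <- x$decomp$eigenvalues
  if (length(ev))
    cat(sprintf("  eigenvalues: %s\n", paste(signif(ev, 4), collapse = ", ")))
  invisible(x)
}

#' Project rows as supplementary elements
#'
#' `H = X W Q`: new observations are projected onto the discriminant factor
#' space. If `preprocessed = FALSE` (default) the model's stored
#' preprocessing parameters are applied first, so held-out rows are
#' transformed with training parameters only.
#'
#' @param model a fitted `bada` model.
#' @param x matrix of rows to project (raw scale unless `preprocessed`).
#' @param preprocessed set `TRUE` if `x` is already on the preprocessed
#'   scale of `model$Xp`.
#' @return an `n x L` matrix of factor scores.
#' @export
project_rows <- function(model, x, preprocessed = FALSE) {
  stopifnot(inherits(model, "bada"))
  x <- check_numeric_matrix(x)
  if (ncol(x) != nrow(model$G))
    stop_("x has %d columns, model expects %d", ncol(x), nrow(model$G))
  if (!preprocessed) x <- apply_preprocess(model$preprocess, x)
  H <- x %*% model$WQ
  colnames(H) <- colnames(model$F)
  H
}

#' Squared Euclidean distances to the category barycenters in factor space
#'
#' @param H `n x L` observation factor scores.
#' @param F `I x L` category factor scores.
#' @return an `n x I` matrix of squared distances.
#' @export
score_distances <- function(H, F) {
  H <- as.matrix(H)
  F <- as.matrix(F)
  if (ncol(H) != ncol(F)) stop_("H and F must have the same number of dimensions")
  d2 <- outer(rowSums(H^2), rep(1, nrow(F))) +
    outer(rep(1, nrow(H)), rowSums(F^2)) - 2 * H %*% t(F)
  pmax(d2, 0)
}

#' Nearest-barycenter classification
#'
#' Each observation is assigned to the category whose factor scores are
#' closest in (squared) Euclidean distance in the factor space. Exact ties
#' are broken deterministically in favor of the lowest category index and
#' flagged. By default the training observations are classified (the fixed
#' effect model); pass new rows for supplementary classification.
#'
#' The confusion matrix has actual categories in columns and predicted
#' categories in rows, so column sums equal the category sizes.
#'
#' @param model a fitted `bada` model.
#' @param newdata optional matrix of raw rows to classify instead of the
#'   training observations.
#' @param actual optional actual labels for `newdata` (for a confusion
#'   matrix).
#' @param n_components number of leading dimensions used for distances;
#'   default the model's setting, or all.
#' @return an object of class `bada_classification` with elements
#'   `distances`, `assigned`, `ties`, `confusion`, `accuracy`,
#'   `category_accuracy` and `mode`.
#' @export
classify <- function(model, newdata = NULL, actual = NULL, n_components = NULL) {
  stopifnot(inherits(model, "bada"))
  if (is.null(newdata)) {
    H <- model$H
    actual <- actual %||% model$row_categories
    mode <- "fixed"
  } else {
    H <- project_rows(model, newdata)
    mode <- "supplementary"
  }
  L <- n_components %||% model$n_components %||% ncol(H)
  L <- min(L, ncol(H))
  report <- classification_report(H[, seq_len(L), drop = FALSE],
                                  model$F[, seq_len(L), drop = FALSE],
                                  model$categories, actual, mode)
  report
}

# Shared by classify() and crossvalidate(): argmin assignment with
# deterministic tie-break, confusion and accuracy bookkeeping.
classification_report <- function(H, F, categories, actual, mode) {
  d2 <- score_distances(H, F)
  colnames(d2) <- categories
  near <- d2 <= apply(d2, 1, min) + 1e-12 * pmax(apply(d2, 1, min), 1)
  ties <- rowSums(near) > 1
  # lowest category index among the (near-)minimal distances
  assigned <- factor(categories[apply(near, 1, which.max)],
                     levels = categories)
  if (any(ties))
    warning(sprintf("%d tie(s) broken in favor of the lowest category index",
                    sum(ties)), call. = FALSE)
  confusion <- NULL
  accuracy <- NULL
  category_accuracy <- NULL
  if (!is.null(actual)) {
    actual <- factor(as.character(actual), levels = categories)
    confusion <- table(predicted = assigned, actual = actual)
    accuracy <- mean(assigned == actual)
    category_accuracy <- diag(unclass(confusion)) / colSums(confusion)
  }
  structure(list(distances = d2, assigned = assigned, ties = ties,
                 confusion = confusion, accuracy = accuracy,
                 category_accuracy = category_accuracy, mode = mode),
            class = "bada_classification")
}

#' @export
print.bada_classification <- function(x, ...) {
  cat(sprintf("bada classification (%s effect)\n", x$mode))
  if (!is.null(x$confusion)) {
    print(x$confusion)
    cat(sprintf("accuracy: %.3f\n", x$accuracy))
  }
  invisible(x)
}

#' Variable loadings
#'
#' Three conventional descriptions of the variables' role in the category
#' separation: the right generalized singular vectors `Q`, the variable
#' factor scores `G = Q diag(delta)` (same vectors scaled by the singular
#' values), or the mass-weighted correlation between each column of the
#' barycenter matrix and each dimension's category factor scores.
#'
#' @param model a fitted `bada` model.
#' @param kind `"G"`, `"Q"` or `"correlation"`.
#' @return a `J x L` matrix.
#' @export
bada_loadings <- function(model, kind = c("G", "Q", "correlation")) {
  stopifnot(inherits(model, "bada"))
  kind <- match.arg(kind)
  switch(kind,
    G = model$G,
    Q = model$decomp$Q,
    correlation = {
      bw <- model$b / sum(model$b)
      Rc <- sweep(model$R, 2, colSums(model$R * bw), "-")
      Fc <- sweep(model$F, 2, colSums(model$F * bw), "-")
      sdR <- sqrt(colSums(Rc^2 * bw))
      zero <- which(sdR <= 0)
      if (length(zero))
        stop_("column %d of the barycenter matrix has zero variance", zero[1])
      sdF <- sqrt(colSums(Fc^2 * bw))
      cor <- t(Rc * bw) %*% Fc / outer(sdR, sdF)
      dimnames(cor) <- list(rownames(model$G), colnames(model$F))
      cor
    })
}
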