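#' Inertia decomposition and discrimination R-squared
#'
#' The total inertia of the observation factor scores about the grand
#' barycenter splits additively into the inertia of the observations about
#' their own category barycenters (within) and the inertia of the category
#' barycenters about the grand barycenter (between):
#' `total = within + between`. The ratio `R2 = between / total` plays the
#' role of the proportion of variance explained by the categories, as in
#' the analysis-of-variance sum-of-squares decomposition.
#'
#' The grand barycenter is the category-mass-weighted mean of the category
#' factor scores (equivalently the row-mass-weighted mean of the
#' observation scores), which is what makes the decomposition exact.
#'
#' @param model a fitted `bada` model.
#' @param H optional observation factor scores; default the model's
#'   training scores.
#' @param categories,masses optional labels and masses matching `H`;
#'   default the training design.
#' @return an object of class `bada_inertia` with `total`, `within`,
#'   `between`, `r_squared` and `grand_barycenter`. A degenerate fit with
#'   zero total inertia reports `r_squared = 0`.
#' @export
inertia_decomposition <- function(model, H = NULL, categories = NULL,
                                  masses = NULL) {
  stopifnot(inherits(model, "bada"))
  H <- H %||% model$H
  categories <- categories %||% model$row_categories
  masses <- masses %||% model$m
  F <- model$F
  b <- model$b
  fbar <- colSums(F * (b / sum(b)))
  total <- sum(masses * rowSums(sweep(H, 2, fbar, "-")^2))
  Fi <- F[as.integer(factor(as.character(categories), levels = model$categories)), ,
          drop = FALSE]
  within <- sum(masses * rowSums((H - Fi)^2))
  between <- sum(b * rowSums(sweep(F, 2, fbar, "-")^2))
  r2 <- if (total > .Machine$double.eps) between / total else 0
  structure(list(total = total, within = within, between = between,
                 r_squared = r2, grand_barycenter = fbar),
            class = "bada_inertia")
}

#' @export
print.bada_inertia <- function(x, ...) {
  cat(sprintf("inertia: total %.6g = within %.6g + between %.6g;  R2 = %.4f\n",
              x$total, x$within, x$between, x$r_squared))
  invisible(x)
}

# Refit after a label permutation without redoing the (label-independent)
# preprocessing; returns the permuted-fit R2. Used by permutation_test for
# variants whose weights do not depend on the labels.
refit_r2 <- function(model, new_categories) {
  m <- model$m
  b <- as.numeric(tapply(m, new_categories, sum))
  R <- compute_barycenters(model$Xp, new_categories, m)
  dec <- gsvd(R, b, model$w)
  if (dec$L == 0) return(0)
  F <- dec$P %*% diag(dec$delta, dec$L)
  H <- model$Xp %*% weight_times(model$w, dec$Q)
  fbar <- colSums(F * (b / sum(b)))
  total <- sum(m * rowSums(sweep(H, 2, fbar, "-")^2))
  between <- sum(b * rowSums(sweep(F, 2, fbar, "-")^2))
  if (total > .Machine$double.eps) between / total else 0
}

#' Permutation test of the discrimination R-squared
#'
#' Category labels are permuted at the exchangeable-unit level -- whole
#' blocks when a block design is present (scans within a block are
#' correlated, so observations are not exchangeable), otherwise single
#' observations -- the model is refitted, and the observed `R2` is compared
#' with its permutation null distribution. The p-value uses the add-one
#' estimator `p = (1 + #(R2* >= R2)) / (1 + n_permutations)`, which never
#' reports zero and is valid for a finite number of permutations.
#'
#' @param table a [discriminant_table()].
#' @param variant,steps passed to [bada()].
#' @param n_permutations at least 99; default 999.
#' @param seed optional integer seed.
#' @param units `"auto"` (blocks when present), `"block"` or
#'   `"observation"`.
#' @return list with `p_value`, `r_squared` (observed), `null` (the
#'   permutation distribution) and `n_permutations`.
#' @export
permutation_test <- function(table, variant = "plain", steps = NULL,
                             n_permutations = 999, seed = NULL,
                             units = c("auto", "block", "observation")) {
  stopifnot(inherits(table, "discriminant_table"))
  units <- match.arg(units)
  if (n_permutations < 99) stop_("n_permutations must be at least 99")
  if (!is.null(seed)) set.seed(seed)

  model <- bada(table, variant = variant, steps = steps)
  obs <- inertia_decomposition(model)$r_squared

  cats <- table$row_categories
  blocks <- table$row_blocks
  use_blocks <- (units == "block") ||
    (units == "auto" && !is.null(blocks))
  if (units == "block" && is.null(blocks))
    stop_("block-level permutation requested but the table has no blocks")
  if (use_blocks) {
    block_cat <- tapply(as.character(cats), blocks, function(z) {
      u <- unique(z)
      if (length(u) > 1) stop_("a block spans several categories")
      u
    })
    if (length(block_cat) < nlevels(cats))
      stop_("fewer exchangeable units (%d) than categories (%d)",
            length(block_cat), nlevels(cats))
    block_of <- as.integer(blocks)
  } else if (length(cats) < nlevels(cats)) {
    stop_("fewer exchangeable units than categories")
  }

  full_refit <- model$variant == "classical"
  null <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    newcats <- if (use_blocks) {
      factor(sample(block_cat)[block_of], levels = levels(cats))
    } else {
      sample(cats)
    }
    null[p] <- if (full_refit) {
      t2 <- discriminant_table(table$data, newcats, table$row_blocks,
                               table$col_subtables, table$row_masses,
                               table$col_weights)
      inertia_decomposition(bada(t2, variant = variant, steps = steps))$r_squared
    } else {
      refit_r2(model, newcats)
    }
  }
  p_value <- (1 + sum(null >= obs - 1e-12)) / (1 + n_permutations)
  list(p_value = p_value, r_squared = obs, null = null,
       n_permutations = n_permutations)
}

#' Cross-validated (random effect) classification
#'
#' Estimates the model's performance on new observations. For each fold
#' (one observation for `"loo"`, one whole block for `"block"`), the
#' preprocessing parameters and the discriminant model are re-estimated on
#' the retained rows only; the held-out rows are preprocessed with those
#' training parameters, projected onto the fold's factor space
#' (`h = x W_fold Q_fold`), and assigned to the nearest fold barycenter.
#' Leave-one-block-out is the appropriate scheme when scans within a block
#' are temporally correlated: plain leave-one-out then leaks information
#' through the correlated blockmates and overestimates accuracy.
#'
#' For prediction-interval displays each held-out row is also carried back
#' into the full-model factor space by reconstruction
#' (`h_hat = x W_fold Q_fold t(Q_fold) W Q`), giving a cloud of held-out
#' projections comparable across folds.
#'
#' @param table a [discriminant_table()].
#' @param variant,steps passed to [bada()].
#' @param cv_mode `"loo"` or `"block"`.
#' @return an object of class `bada_classification` (mode `"random"`) with
#'   additional elements `hhat` (held-out projections in the full factor
#'   space) and `folds`.
#' @export
crossvalidate <- function(table, variant = "plain", steps = NULL,
                          cv_mode = c("loo", "block")) {
  stopifnot(inherits(table, "discriminant_table"))
  cv_mode <- match.arg(cv_mode)
  N <- nrow(table$data)
  cats <- table$row_categories
  if (cv_mode == "block") {
    if (is.null(table$row_blocks))
      stop_("leave-one-block-out requires block labels")
    folds <- split(seq_len(N), table$row_blocks)
  } else {
    folds <- as.list(seq_len(N))
  }

  full <- bada(table, variant = variant, steps = steps)
  Lfull <- full$decomp$L
  assigned <- character(N)
  dist_min <- numeric(N)
  hhat <- matrix(NA_real_, N, Lfull)
  ties <- logical(N)

  for (f in folds) {
    left <- table(cats[-f])
    if (any(left == 0))
      stop_("fold empties category '%s'", names(left)[which(left == 0)[1]])
    fit <- bada(table_subset(table, setdiff(seq_len(N), f)),
                variant = variant, steps = steps)
    ht <- project_rows(fit, table$data[f, , drop = FALSE])
    d2 <- score_distances(ht, fit$F)
    mins <- apply(d2, 1, min)
    near <- d2 <= mins + 1e-12 * pmax(mins, 1)
    ties[f] <- rowSums(near) > 1
    assigned[f] <- fit$categories[apply(near, 1, which.max)]
    dist_min[f] <- mins
    # reconstruct in the fold basis, then project into the full solution
    hhat[f, ] <- (ht %*% t(fit$decomp$Q)) %*% full$WQ
  }

  assigned <- factor(assigned, levels = full$categories)
  actual <- factor(as.character(cats), levels = full$categories)
  confusion <- table(predicted = assigned, actual = actual)
  structure(list(
    distances = NULL, assigned = assigned, ties = ties,
    confusion = confusion, accuracy = mean(assigned == actual),
    category_accuracy = diag(unclass(confusion)) / colSums(confusion),
    mode = "random", cv_mode = cv_mode, hhat = hhat,
    folds = folds
  ), class = "bada_classification")
}

#' Project a held-out row into the full factor space by reconstruction
#'
#' Two-step projection used for prediction intervals: the row is projected
#' onto the reduced (fold) model, reconstructed from those factor scores
#' (`x_tilde = h_tilde t(Q_fold)`), and the reconstruction is projected as
#' a supplementary element in the full solution, giving
#' `h_hat = x W_fold Q_fold t(Q_fold) W Q`. When the fold basis spans the
#' same space as the full basis, `h_hat` equals the direct projection.
#'
#' @param model_full the model fitted on all observations.
#' @param model_minus the model fitted without the held-out row(s).
#' @param x raw held-out row(s), `n x J`.
#' @return an `n x L_full` matrix of factor scores.
#' @export
project_leftout <- function(model_full, model_minus, x) {
  stopifnot(inherits(model_full, "bada"), inherits(model_minus, "bada"))
  ht <- project_rows(model_minus, x)
  (ht %*% t(model_minus$decomp$Q)) %*% model_full$WQ
}

#' Bootstrap the category barycenters
#'
#' Resamples observations with replacement, stratified within category --
#' and within each category-by-block stratum when the block structure is
#' declared fixed, so the fixed part of the design is never resampled --
#' recomputes the category barycenters of each replicate, and projects
#' them onto the original discriminant factor space (original `W` and `Q`).
#' The spread of the bootstrapped barycenters estimates the sampling
#' variability of the category positions and feeds the confidence
#' ellipses.
#'
#' @param model a fitted `bada` model.
#' @param n_bootstrap at least 100; default 1000.
#' @param fix_blocks resample within category-by-block strata when blocks
#'   are present (default `TRUE`).
#' @param seed optional integer seed.
#' @return an array `n_bootstrap x I x L` of bootstrapped category factor
#'   scores, with category and dimension dimnames.
#' @export
bootstrap_barycenters <- function(model, n_bootstrap = 1000,
                                  fix_blocks = TRUE, seed = NULL) {
  stopifnot(inherits(model, "bada"))
  if (n_bootstrap < 100) stop_("n_bootstrap must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  cats <- model$row_categories
  strata <- if (fix_blocks && !is.null(model$row_blocks)) {
    interaction(cats, model$row_blocks, drop = TRUE)
  } else {
    cats
  }
  idx_by_stratum <- split(seq_along(cats), strata)
  if (any(lengths(idx_by_stratum) == 1))
    warning("stratum with a single observation: resampled trivially",
            call. = FALSE)
  H <- model$H
  m <- model$m
  I <- length(model$categories)
  L <- ncol(H)
  out <- array(NA_real_, c(n_bootstrap, I, L),
               dimnames = list(NULL, model$categories, colnames(H)))
  cat_int <- as.integer(cats)
  for (r in seq_len(n_bootstrap)) {
    idx <- unlist(lapply(idx_by_stratum, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)
    mi <- m[idx]
    ci <- cat_int[idx]
    for (i in seq_len(I)) {
      sel <- idx[ci == i]
      out[r, i, ] <- colSums(H[sel, , drop = FALSE] * m[sel]) / sum(m[sel])
    }
  }
  out
}

#' Multiplicity-corrected confidence level for pairwise category comparisons
#'
#' With `I` categories there are `I (I - 1) / 2` pairwise comparisons, so a
#' nominal per-pair level `1 - alpha` inflates the family-wise type I
#' error. The Bonferroni-corrected level is `1 - 2 alpha / (I (I - 1))`;
#' the Sidak-corrected level is `(1 - alpha)^(1 / (I (I - 1) / 2))`. Both
#' reduce to `1 - alpha` when `I = 2`.
#'
#' @param alpha overall type I error, in (0, 1).
#' @param I number of categories, at least 2.
#' @param method `"none"`, `"bonferroni"` or `"sidak"`.
#' @return the corrected coverage level.
#' @examples
#' corrected_level(0.05, 7, "bonferroni")  # 1 - .1/42
#' @export
corrected_level <- function(alpha, I, method = c("none", "bonferroni", "sidak")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop_("alpha must be a number strictly between 0 and 1")
  if (I < 2) stop_("I must be at least 2")
  switch(method,
    none = 1 - alpha,
    bonferroni = 1 - 2 * alpha / (I * (I - 1)),
    sidak = (1 - alpha)^(1 / (I * (I - 1) / 2)))
}
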