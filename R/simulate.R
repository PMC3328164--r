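#' Specification of a synthetic multi-subject block-design dataset
#'
#' Describes the data regime the method targets: `I` stimulus categories,
#' each presented in `n_blocks` blocks of `scans_per_block` consecutive
#' scans, with `K` subtables of unequal column counts `J_k` (one subtable
#' per subject or ROI). Category effects are mean shifts confined to the
#' `effect_carriers` subtables, with `L2` norm equal to `effect_size`;
#' noise is AR(1) within each block with lag-one correlation
#' `intra_block_rho` (the minimal model of the temporal correlation of
#' consecutive scans), independent across blocks and columns, with
#' stationary marginal standard deviation `noise_sd`.
#'
#' Defaults mirror a seven-category recognition experiment: 7 categories
#' in 8 blocks of 16 scans (896 rows), 10 subtables of unequal size.
#'
#' @param I number of categories.
#' @param n_blocks blocks per category.
#' @param scans_per_block consecutive scans per block.
#' @param K number of subtables.
#' @param J_k integer vector of column counts per subtable (length `K`).
#' @param effect_size norm of each category's mean shift (0 = null data).
#' @param effect_carriers integer indices of the subtables carrying the
#'   category effect; default all.
#' @param intra_block_rho lag-1 autocorrelation of within-block noise, in
#'   `[0, 1)`.
#' @param noise_sd stationary noise standard deviation.
#' @param count_total row total for the multinomial count generator.
#' @param seed integer seed; the same seed reproduces the dataset
#'   bit-for-bit.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(I = 7, n_blocks = 8, scans_per_block = 16, K = 10,
                     J_k = c(28, 48, 30, 44, 34, 46, 32, 42, 36, 40),
                     effect_size = 1, effect_carriers = seq_len(K),
                     intra_block_rho = 0.5, noise_sd = 1,
                     count_total = 300, seed = 1) {
  if (length(J_k) != K) stop_("J_k must have length K = %d", K)
  if (any(c(I, n_blocks, scans_per_block, K, J_k) < 1))
    stop_("all counts must be at least 1")
  if (I < 2) stop_("need at least two categories")
  if (intra_block_rho < 0 || intra_block_rho >= 1)
    stop_("intra_block_rho must be in [0, 1)")
  if (noise_sd < 0) stop_("noise_sd must be nonnegative")
  if (effect_size < 0) stop_("effect_size must be nonnegative")
  effect_carriers <- as.integer(effect_carriers)
  if (length(effect_carriers) &&
      (min(effect_carriers) < 1 || max(effect_carriers) > K))
    stop_("effect_carriers must index the subtables 1..%d", K)
  structure(list(I = I, n_blocks = n_blocks,
                 scans_per_block = scans_per_block, K = K, J_k = J_k,
                 effect_size = effect_size,
                 effect_carriers = effect_carriers,
                 intra_block_rho = intra_block_rho, noise_sd = noise_sd,
                 count_total = count_total, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a synthetic multi-subject scan table
#'
#' Draws one mean-shift vector per category (norm `effect_size`, nonzero
#' only on the carrier subtables' columns) and adds stationary AR(1) noise
#' within each block. Returns the assembled [discriminant_table()] together
#' with the ground truth (the `I x J` matrix of true category means), so
#' recovery tests never have to re-derive it.
#'
#' @param spec a [sim_spec()].
#' @return list with `table` (a `discriminant_table`) and `truth` (list
#'   with `category_means` and the `spec`).
#' @export
simulate_scans <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  J <- sum(spec$J_k)
  subt <- factor(rep(paste0("S", seq_len(spec$K)), spec$J_k),
                 levels = paste0("S", seq_len(spec$K)))
  carrier_cols <- which(as.integer(subt) %in% spec$effect_carriers)

  mu <- matrix(0, spec$I, J)
  if (spec$effect_size > 0 && length(carrier_cols)) {
    for (i in seq_len(spec$I)) {
      v <- stats::rnorm(length(carrier_cols))
      mu[i, carrier_cols] <- v / sqrt(sum(v^2)) * spec$effect_size
    }
  }

  cat_levels <- sprintf("C%d", seq_len(spec$I))
  Tb <- spec$scans_per_block
  n_per_cat <- spec$n_blocks * Tb
  N <- spec$I * n_per_cat
  cats <- factor(rep(cat_levels, each = n_per_cat), levels = cat_levels)
  blocks <- factor(rep(sprintf("C%d.B%d",
                               rep(seq_len(spec$I), each = spec$n_blocks),
                               rep(seq_len(spec$n_blocks), spec$I)),
                       each = Tb))

  rho <- spec$intra_block_rho
  X <- matrix(0, N, J)
  row <- 0
  for (bl in seq_len(spec$I * spec$n_blocks)) {
    E <- matrix(stats::rnorm(Tb * J, sd = spec$noise_sd), Tb, J)
    if (rho > 0 && Tb > 1) {
      fac <- sqrt(1 - rho^2)
      for (t in 2:Tb) E[t, ] <- rho * E[t - 1, ] + fac * E[t, ]
    }
    X[row + seq_len(Tb), ] <- E
    row <- row + Tb
  }
  X <- X + mu[as.integer(cats), ]
  colnames(X) <- sprintf("%s.v%d", as.character(subt), stats::ave(
    rep(1L, J), subt, FUN = seq_along))
  tab <- discriminant_table(X, cats, blocks, subt)
  list(table = tab, truth = list(category_means = mu, spec = spec))
}

#' Generate a synthetic count table for the correspondence-analysis variants
#'
#' Each category has a multinomial probability profile: a common baseline
#' perturbed on the carrier subtables' columns by log-scale shifts of
#' magnitude `effect_size` (zero effect gives identical profiles). Each row
#' is an independent multinomial draw of `count_total` counts from its
#' category profile, laid out in the same blocks-by-category row design as
#' [simulate_scans()].
#'
#' @param spec a [sim_spec()].
#' @return list with `table` (a `discriminant_table` of counts) and
#'   `truth` (list with the `I x J` matrix of true `profiles` and the
#'   `spec`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  J <- sum(spec$J_k)
  subt <- factor(rep(paste0("S", seq_len(spec$K)), spec$J_k),
                 levels = paste0("S", seq_len(spec$K)))
  carrier_cols <- which(as.integer(subt) %in% spec$effect_carriers)

  base <- stats::rgamma(J, shape = 2, rate = 1) + 0.1
  profiles <- matrix(0, spec$I, J)
  for (i in seq_len(spec$I)) {
    eta <- numeric(J)
    if (spec$effect_size > 0 && length(carrier_cols))
      eta[carrier_cols] <- stats::rnorm(length(carrier_cols)) * spec$effect_size
    p <- base * exp(eta)
    profiles[i, ] <- p / sum(p)
  }

  cat_levels <- sprintf("C%d", seq_len(spec$I))
  n_per_cat <- spec$n_blocks * spec$scans_per_block
  cats <- factor(rep(cat_levels, each = n_per_cat), levels = cat_levels)
  blocks <- factor(rep(sprintf("C%d.B%d",
                               rep(seq_len(spec$I), each = spec$n_blocks),
                               rep(seq_len(spec$n_blocks), spec$I)),
                       each = spec$scans_per_block))
  N <- spec$I * n_per_cat
  X <- matrix(0L, N, J)
  for (n in seq_len(N))
    X[n, ] <- stats::rmultinom(1, spec$count_total, profiles[as.integer(cats)[n], ])
  tab <- discriminant_table(X, cats, blocks, subt)
  list(table = tab, truth = list(profiles = profiles, spec = spec))
}
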