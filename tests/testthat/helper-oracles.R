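# Independent oracles and small fixture builders shared across tests.

# Correspondence analysis row scores of a contingency table, coded from the
# chi-square profile decomposition directly (independent of gsvd()).
ca_row_scores <- function(A) {
  P <- A / sum(A)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  keep <- sv$d > 1e-10 * sv$d[1]
  diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], sum(keep))
}

# Brute-force generalized eigenvalues: eigenvalues of
# W^(1/2) R' B R W^(1/2) (cross-product route, independent of the SVD
# back-transform used by gsvd()).
gsvd_eigen_oracle <- function(R, b, w) {
  ws <- sqrt(w)
  M <- (t(R) %*% (b * R))
  M <- sweep(sweep(M, 1, ws, "*"), 2, ws, "*")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sort(ev[ev > max(ev) * 1e-12], decreasing = TRUE)
}

# Align the column signs of B to match A (for comparisons defined up to
# per-dimension reflection).
align_signs <- function(A, B) {
  for (l in seq_len(ncol(A)))
    if (sum(A[, l] * B[, l]) < 0) B[, l] <- -B[, l]
  B
}

# Small deterministic multi-subtable fixture used by several tests.
small_sim <- function(seed = 42, effect = 2, rho = 0.3, I = 3, K = 3,
                      J_k = c(6, 5, 4), n_blocks = 4, scans = 5,
                      carriers = seq_len(K), noise = 1) {
  simulate_scans(sim_spec(I = I, n_blocks = n_blocks,
                          scans_per_block = scans, K = K, J_k = J_k,
                          effect_size = effect, effect_carriers = carriers,
                          intra_block_rho = rho, noise_sd = noise,
                          seed = seed))
}

random_count_table <- function(seed, I = 4, per_cat = 8, J = 6) {
  set.seed(seed)
  lam <- matrix(rgamma(I * J, 2, 0.4) + 0.5, I, J)
  cats <- factor(rep(sprintf("C%d", seq_len(I)), each = per_cat))
  X <- matrix(rpois(I * per_cat * J, lam[as.integer(cats), ]) + 1,
              I * per_cat, J)
  discriminant_table(X, cats)
}
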