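test_that("barycenters are mass-weighted category means", {
  R <- compute_barycenters(rbind(c(1, 2), c(3, 4), c(5, 6)), c("A", "A", "B"))
  expect_equal(unname(R), rbind(c(2, 3), c(5, 6)))
  # single category, non-uniform masses
  R2 <- compute_barycenters(rbind(c(4, 0), c(0, 4), c(8, 8)), rep("A", 3),
                            masses = c(0.5, 0.25, 0.25))
  expect_equal(unname(R2), matrix(c(4, 3), 1))
  # all rows identical
  R3 <- compute_barycenters(matrix(7, 4, 2), c("a", "a", "b", "b"))
  expect_equal(unname(R3), matrix(7, 2, 2))
  expect_error(compute_barycenters(diag(2), c("a", "b"), masses = c(1, 0)),
               "zero total mass")
})

test_that("rank bounds and refit determinism hold", {
  # two well-separated categories in 2 variables: one dimension after centering
  tab <- discriminant_table(rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.2, 5)),
                            c("a", "a", "b", "b"))
  expect_equal(bada(tab)$decomp$L, 1)
  sim <- small_sim(seed = 31, I = 4)
  fit <- bada(sim$table)
  expect_lte(fit$decomp$L, min(4 - 1, ncol(sim$table$data)))
  fit2 <- bada(sim$table)
  expect_identical(fit$F, fit2$F)
  expect_identical(fit$decomp$delta, fit2$decomp$delta)
})

test_that("the barycentric property of supplementary projections is exact for every variant", {
  scans <- small_sim(seed = 32)
  counts <- simulate_counts(sim_spec(I = 3, n_blocks = 3, scans_per_block = 4,
                                     K = 2, J_k = c(5, 4), effect_size = 0.5,
                                     seed = 33))
  fits <- list(
    plain = bada(scans$table),
    pipeline = bada(scans$table, steps = c("center", "mfa", "row_ss")),
    dica = bada(counts$table, variant = "dica"),
    hellinger = bada(counts$table, variant = "hellinger"),
    classical = bada(scans$table, variant = "classical")
  )
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    Hbar <- compute_barycenters(fit$H, fit$row_categories, fit$m)
    expect_lt(max(abs(Hbar - fit$F)), 1e-10)
    # projecting the barycenters themselves returns F exactly
    expect_lt(max(abs(project_rows(fit, fit$R, preprocessed = TRUE) - fit$F)),
              1e-10)
    # per-dimension B-weighted variance of F equals the eigenvalue
    expect_lt(max(abs(t(fit$F) %*% (fit$b * fit$F) -
                        diag(fit$decomp$eigenvalues, fit$decomp$L))), 1e-10)
  }
})

test_that("a supplementary row equal to a barycenter lands on its factor scores", {
  sim <- small_sim(seed = 34)
  fit <- bada(sim$table)
  h <- project_rows(fit, fit$R[2, , drop = FALSE], preprocessed = TRUE)
  expect_equal(unname(h[1, ]), unname(fit$F[2, ]), tolerance = 1e-10)
})

test_that("dica equals correspondence analysis of the aggregated table", {
  for (seed in c(1, 2, 3)) {
    tab <- random_count_table(seed)
    fit <- bada(tab, variant = "dica")
    A <- rowsum(tab$data, tab$row_categories)
    Fca <- align_signs(fit$F, ca_row_scores(A))
    expect_lt(max(abs(fit$F - Fca)), 1e-8)
  }
  # no category effect: identical count rows give no discrimination
  flat <- discriminant_table(matrix(10, 4, 2), c("a", "a", "b", "b"))
  expect_equal(bada(flat, variant = "dica")$decomp$L, 0)
})

test_that("distance computation and assignment follow the nearest-barycenter rule", {
  F <- rbind(c(0, 0), c(2, 0))
  h <- matrix(c(0.9, 5), 1)
  d2 <- score_distances(h, F)
  expect_equal(unname(d2[1, ]), c(25.81, 26.21))
  sim <- small_sim(seed = 35, effect = 3)
  fit <- bada(sim$table)
  # classifying the barycenters themselves: diagonal confusion
  rep_b <- classify(fit, newdata = NULL)
  expect_equal(unname(project_rows(fit, fit$R, preprocessed = TRUE)),
               unname(fit$F), tolerance = 1e-10)
  db <- score_distances(fit$F, fit$F)
  expect_equal(unname(apply(db, 1, which.min)), seq_len(nrow(fit$F)))
  expect_true(rep_b$accuracy > 0.9)
  # column sums of the confusion equal the category sizes
  expect_equal(unname(colSums(rep_b$confusion)),
               unname(as.numeric(table(sim$table$row_categories))))
})

test_that("exact ties go to the lowest category index with a warning", {
  tab <- discriminant_table(rbind(c(-1, 0), c(-1, 0.5), c(1, 0), c(1, 0.5)),
                            c("a", "a", "b", "b"))
  fit <- bada(tab)
  equidistant <- matrix(c(0, 0.25), 1)  # midway between the barycenters
  expect_warning(rep <- classify(fit, newdata = equidistant), "tie")
  expect_equal(as.character(rep$assigned), "a")
  expect_true(rep$ties[1])
})

test_that("zero-effect data classifies near chance", {
  acc <- vapply(1:5, function(s) {
    sim <- small_sim(seed = 100 + s, effect = 0, rho = 0)
    classify(bada(sim$table))$accuracy
  }, numeric(1))
  # fixed-effect accuracy on null data stays near 1/I = 1/3 (well below 1)
  expect_lt(mean(acc), 0.65)
  expect_gt(mean(acc), 1 / 3 - 0.1)
})

test_that("loadings kinds are consistent and correlations bounded", {
  sim <- small_sim(seed = 36)
  fit <- bada(sim$table)
  G <- bada_loadings(fit, "G")
  Q <- bada_loadings(fit, "Q")
  expect_equal(G, Q %*% diag(fit$decomp$delta, fit$decomp$L),
               ignore_attr = TRUE, tolerance = 1e-12)
  cors <- bada_loadings(fit, "correlation")
  expect_true(all(abs(cors) <= 1 + 1e-10))
  # two-variable toy: the variable with the larger barycenter separation
  # carries the larger |G| on the single dimension
  toy <- discriminant_table(rbind(c(0, 0), c(0.2, 0.1), c(4, 1), c(4.2, 1.1)),
                            c("a", "a", "b", "b"))
  tfit <- bada(toy)
  expect_gt(abs(tfit$G[1, 1]), abs(tfit$G[2, 1]))
})
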