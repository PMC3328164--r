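test_that("inertia decomposition matches hand arithmetic and is additive", {
  # 4 observations at +-1 around barycenters at -2 and 2, one dimension
  tab <- discriminant_table(matrix(c(-3, -1, 1, 3), 4, 1), c("a", "a", "b", "b"))
  fit <- bada(tab, steps = character(0))
  ine <- inertia_decomposition(fit)
  # factor scores are w-scaled; undo the uniform weight 1/J = 1 here
  expect_equal(ine$within, 1 * fit$w[1])
  expect_equal(ine$between, 4 * fit$w[1])
  expect_equal(ine$total, 5 * fit$w[1])
  expect_equal(ine$r_squared, 0.8)
  # degenerate cases
  sim <- small_sim(seed = 41)
  f2 <- bada(sim$table)
  ine2 <- inertia_decomposition(f2)
  expect_equal(ine2$total, ine2$within + ine2$between,
               tolerance = 1e-8)
  # observations equal to their barycenter: within = 0, R2 = 1
  tab3 <- discriminant_table(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
                             c("a", "a", "b", "b"))
  expect_equal(inertia_decomposition(bada(tab3))$r_squared, 1)
  # all barycenters equal: between = 0, R2 = 0
  tab4 <- discriminant_table(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                             c("a", "a", "b", "b"))
  expect_equal(inertia_decomposition(bada(tab4))$r_squared, 0, tolerance = 1e-12)
})

test_that("additivity holds across variants on simulated fits", {
  counts <- simulate_counts(sim_spec(I = 3, n_blocks = 3, scans_per_block = 4,
                                     K = 2, J_k = c(5, 4), effect_size = 0.6,
                                     seed = 42))
  scans <- small_sim(seed = 43)
  for (fit in list(bada(counts$table, variant = "dica"),
                   bada(counts$table, variant = "hellinger"),
                   bada(scans$table, variant = "classical"),
                   bada(scans$table, steps = c("center", "mfa", "row_ss")))) {
    ine <- inertia_decomposition(fit)
    expect_equal(ine$total, ine$within + ine$between, tolerance = 1e-8)
  }
})

test_that("the permutation test is deterministic given a seed and saturates on strong effects", {
  sim <- small_sim(seed = 44, effect = 6, rho = 0)
  pt1 <- permutation_test(sim$table, n_permutations = 99, seed = 5)
  pt2 <- permutation_test(sim$table, n_permutations = 99, seed = 5)
  expect_identical(pt1$null, pt2$null)
  expect_equal(pt1$p_value, 1 / 100)  # minimum attainable value
  expect_length(pt1$null, 99)
})

test_that("identical rows give R2 = 0 and p = 1", {
  tab <- discriminant_table(matrix(1, 8, 3), rep(c("a", "b"), each = 4),
                            row_blocks = rep(1:4, each = 2))
  pt <- permutation_test(tab, n_permutations = 99, seed = 1)
  expect_equal(pt$r_squared, 0)
  expect_equal(pt$p_value, 1)
})

test_that("permutation errors on too few exchangeable units", {
  tab <- discriminant_table(matrix(rnorm(12), 4, 3), c("a", "a", "b", "b"),
                            row_blocks = c(1, 1, 2, 2))
  expect_no_error(permutation_test(tab, n_permutations = 99, seed = 1))
  tab3 <- discriminant_table(matrix(rnorm(18), 6, 3),
                             c("a", "a", "b", "b", "c", "c"),
                             row_blocks = c(1, 1, 1, 1, 2, 2))
  expect_error(permutation_test(tab3, n_permutations = 99),
               "exchangeable units|spans")
})

test_that("cross-validation with duplicated rows equals the fixed-effect fit", {
  set.seed(45)
  x <- matrix(rnorm(8 * 4), 8, 4)
  x[5:8, ] <- x[5:8, ] + 3  # separated categories
  x <- rbind(x, x)  # every row duplicated once
  cats <- factor(rep(rep(c("a", "b"), each = 4), 2))
  tab <- discriminant_table(x, cats)
  cv <- crossvalidate(tab, cv_mode = "loo")
  fixed <- classify(bada(tab))
  expect_equal(cv$accuracy, fixed$accuracy)
  expect_equal(as.character(cv$assigned), as.character(fixed$assigned))
})

test_that("held-out projections never use held-out statistics", {
  sim <- small_sim(seed = 46, I = 2, n_blocks = 3)
  tab <- sim$table
  # corrupt one block; folds that exclude it must be unchanged
  idx_block1 <- which(tab$row_blocks == levels(tab$row_blocks)[1])
  tab2 <- tab
  tab2$data[idx_block1, ] <- tab2$data[idx_block1, ] * 1000 + 5
  rest <- setdiff(seq_len(nrow(tab$data)), idx_block1)
  f1 <- bada(table_subset(tab, rest))
  f2 <- bada(table_subset(tab2, rest))
  expect_identical(f1$preprocess, f2$preprocess)
  expect_identical(f1$decomp$Q, f2$decomp$Q)
  expect_identical(f1$w, f2$w)
})

test_that("a fold that empties a category is a named error", {
  tab <- discriminant_table(matrix(rnorm(12), 4, 3), c("a", "a", "a", "b"),
                            row_blocks = c(1, 1, 2, 3))
  expect_error(crossvalidate(tab, cv_mode = "block"), "'b'")
})

test_that("reconstruction projection is a fixed point when the fold basis spans the space", {
  # three categories in two variables, no preprocessing: the (uncentered)
  # barycenters span all of R^2, so Q_fold is a W-orthonormal basis of the
  # whole variable space and the two-step projection reduces to the direct one
  set.seed(47)
  x <- matrix(rnorm(12 * 2), 12, 2) + rep(c(0, 4, 8), each = 4)
  cats <- factor(rep(c("a", "b", "c"), each = 4))
  tab <- discriminant_table(x, cats)
  full <- bada(tab, steps = character(0))
  minus <- bada(table_subset(tab, -1), steps = character(0))
  expect_equal(minus$decomp$L, 2)
  hhat <- project_leftout(full, minus, tab$data[1, , drop = FALSE])
  h <- project_rows(full, tab$data[1, , drop = FALSE])
  expect_equal(unname(hhat), unname(h), tolerance = 1e-9)
  # a row equal to a barycenter untouched by the fold lands on that
  # barycenter's full-model factor scores
  hb <- project_leftout(full, minus, full$R["c", , drop = FALSE])
  expect_equal(unname(hb[1, ]), unname(full$F["c", ]), tolerance = 1e-9)
})

test_that("bootstrapped barycenters are consistent and respect degenerate variance", {
  sim <- small_sim(seed = 48, effect = 2)
  fit <- bada(sim$table)
  boot <- bootstrap_barycenters(fit, n_bootstrap = 200, seed = 9)
  expect_equal(dim(boot), c(200, 3, fit$decomp$L))
  for (i in 1:3) for (l in seq_len(fit$decomp$L)) {
    se <- stats::sd(boot[, i, l])
    expect_lt(abs(mean(boot[, i, l]) - fit$F[i, l]), 3 * se + 1e-12)
  }
  # zero within-category variance: every bootstrapped barycenter equals F
  tabz <- discriminant_table(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
                             c("a", "a", "b", "b"))
  fz <- bada(tabz)
  bz <- bootstrap_barycenters(fz, n_bootstrap = 100, seed = 2)
  expect_lt(max(abs(sweep(bz, 2:3, fz$F))), 1e-12)
  # determinism
  expect_identical(boot, bootstrap_barycenters(fit, n_bootstrap = 200, seed = 9))
})

test_that("multiplicity-corrected levels match the closed forms", {
  expect_equal(corrected_level(0.05, 2, "bonferroni"), 0.95)
  expect_equal(corrected_level(0.05, 2, "sidak"), 0.95)
  expect_equal(corrected_level(0.05, 7, "bonferroni"), 1 - 0.1 / 42)
  expect_equal(corrected_level(0.05, 7, "sidak"), 0.95^(1 / 21))
  expect_equal(corrected_level(0.05, 4, "none"), 0.95)
  expect_error(corrected_level(1.5, 3), "alpha")
  expect_error(corrected_level(0.05, 1), "at least 2")
})
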