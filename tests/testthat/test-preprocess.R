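test_that("centering stores means and applies them to new rows", {
  res <- center_columns(matrix(c(1, 2, 3, 2, 2, 2), 3, 2))
  expect_equal(res$x[, 1], c(-1, 0, 1))
  expect_equal(res$x[, 2], c(0, 0, 0))
  expect_equal(unname(res$params$means), c(2, 2))
  newx <- apply_preprocess(list(res$params), matrix(c(2, 2), 1, 2))
  expect_equal(unname(newx), matrix(0, 1, 2))
})

test_that("z-scoring uses the population denominator and training parameters", {
  res <- zscore_columns(matrix(c(0, 2), 2, 1))
  expect_equal(res$x[, 1], c(-1, 1))  # sd = 1 with denominator N
  expect_error(zscore_columns(cbind(a = c(1, 2), b = c(3, 3))),
               "zero-variance column: b")
  # out-of-sample contract: training parameters, not joint restandardization
  train <- matrix(c(0, 2, 1, 5), 2, 2)
  f <- fit_preprocess(train, "zscore")
  new_row <- matrix(c(4, 9), 1, 2)
  out <- apply_preprocess(f$steps, new_row)
  joint <- fit_preprocess(rbind(train, new_row), "zscore")$x[3, , drop = FALSE]
  expect_equal(unname(out), unname((new_row - c(1, 3)) / c(1, 2)))
  expect_false(isTRUE(all.equal(out, joint)))
  # params are a function of the training rows only
  expect_equal(f$steps, fit_preprocess(train, "zscore")$steps)
})

test_that("row normalization matches hand arithmetic and rejects zero rows", {
  expect_equal(normalize_rows(matrix(c(3, 4), 1), "sum_of_squares"),
               matrix(c(0.6, 0.8), 1))
  expect_equal(normalize_rows(matrix(c(1, 1, 2), 1), "sum"),
               matrix(c(0.25, 0.25, 0.5), 1))
  u <- matrix(c(0.6, 0.8), 1)
  expect_equal(normalize_rows(u, "sum_of_squares"), u)
  expect_error(normalize_rows(matrix(c(0, 0), 1), "sum_of_squares"), "row 1")
  expect_error(normalize_rows(matrix(c(1, -1), 1), "sum"), "row 1")
})

test_that("hellinger transform puts rows on the unit sphere", {
  expect_equal(hellinger_transform(matrix(1, 1, 4)), matrix(0.5, 1, 4))
  expect_equal(hellinger_transform(matrix(c(9, 16), 1)),
               matrix(c(0.6, 0.8), 1))
  set.seed(3)
  x <- matrix(rpois(50, 4) + 1, 5, 10)
  h <- hellinger_transform(x)
  expect_equal(rowSums(h^2), rep(1, 5))
  expect_error(hellinger_transform(matrix(c(-1, 2), 1)), "negative")
  expect_error(hellinger_transform(matrix(c(0, 0), 1)), "zero total")
})

test_that("MFA normalization sets each subtable's first singular value to one", {
  set.seed(4)
  x <- cbind(matrix(rnorm(40), 10, 4) * 5, matrix(rnorm(30), 10, 3))
  sub <- factor(rep(c("a", "b"), c(4, 3)))
  res <- mfa_normalize_subtables(x, sub)
  for (k in levels(sub)) {
    d1 <- svd(res$x[, sub == k])$d[1]
    expect_equal(d1, 1, tolerance = 1e-10)
  }
  # round trip: rescaling by the stored divisors recovers the input
  back <- sweep(res$x, 2, res$scales[as.integer(sub)], "*")
  expect_equal(back, x, tolerance = 1e-12)
  # scale invariance: a global rescaling of one subtable changes nothing
  x2 <- x
  x2[, sub == "a"] <- x2[, sub == "a"] * 17
  expect_equal(mfa_normalize_subtables(x2, sub)$x, res$x, tolerance = 1e-10)
})

test_that("RV matrix has unit diagonal, is scale invariant, and symmetric case gives equal weights", {
  set.seed(5)
  xa <- matrix(rnorm(40), 10, 4)
  x <- cbind(xa, xa * 3)
  sub <- factor(rep(c("a", "b"), each = 4))
  sw <- statis_weights(x, sub)
  expect_equal(diag(sw$rv), c(a = 1, b = 1))
  expect_equal(sw$rv["a", "b"], 1)  # scalar multiple of the same subtable
  expect_equal(unname(sw$weights), c(0.5, 0.5))
  expect_equal(sum(sw$weights), 1)
  # distinct subtables with equal mutual RV: still equal weights for K = 2
  xb <- matrix(rnorm(40), 10, 4)
  sw2 <- statis_weights(cbind(xa, xb), sub)
  expect_equal(unname(sw2$weights), c(0.5, 0.5))
  expect_error(statis_weights(xa, factor(rep("a", 4))), "at least two")
})

test_that("fitted pipelines replay exactly and never read test-row statistics", {
  sim <- small_sim(seed = 21)
  x <- sim$table$data
  f <- fit_preprocess(x, c("center", "mfa", "row_ss"),
                      subtables = sim$table$col_subtables)
  expect_equal(apply_preprocess(f$steps, x), f$x, tolerance = 1e-12)
  # mutating held-out rows leaves the fitted parameters untouched
  f2 <- fit_preprocess(x, c("center", "mfa", "row_ss"),
                       subtables = sim$table$col_subtables)
  expect_identical(f$steps, f2$steps)
  out1 <- apply_preprocess(f$steps, x[1:2, ] + 100)
  expect_identical(f$steps, f2$steps)
  expect_false(isTRUE(all.equal(out1, f$x[1:2, ])))
})
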