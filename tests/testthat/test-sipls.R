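test_that("the interval partition balances lengths, remainder first", {
  p <- partition_intervals(2071, 25)
  expect_equal(sum(p$length), 2071)
  expect_equal(sum(p$length == 83), 21)
  expect_equal(sum(p$length == 82), 4)
  expect_equal(p$length[1:21], rep(83, 21))
  expect_equal(partition_intervals(10, 10)$length, rep(1, 10))
  expect_equal(partition_intervals(10, 3)$length, c(4, 3, 3))
  expect_error(partition_intervals(10, 1), "n_intervals")
  expect_error(partition_intervals(10, 11), "n_intervals")
})

test_that("every variable is covered exactly once for arbitrary (n, k)", {
  for (n in c(17, 100, 399)) for (k in c(2, 7, 10)) {
    p <- partition_intervals(n, k)
    covered <- unlist(mapply(seq, p$start, p$end, SIMPLIFY = FALSE))
    expect_equal(covered, seq_len(n))
    expect_lte(max(p$length) - min(p$length), 1)
  }
})

test_that("combination enumeration is exhaustive and ordered", {
  expect_length(enumerate_combos(25, c(2, 3)), 2600)
  expect_length(enumerate_combos(25, 2), 300)
  expect_equal(enumerate_combos(3, 2), list(c(1, 2), c(1, 3), c(2, 3)))
  cs <- enumerate_combos(6, c(2, 3))
  expect_false(any(duplicated(sapply(cs, paste, collapse = "-"))))
  expect_error(enumerate_combos(5, integer(0)), "nonempty")
})

test_that("a combination covering all variables equals full-spectrum PLS", {
  set.seed(1)
  g <- make_grid(600, 639, 1, dialect = "inclusive_points")
  X <- matrix(rnorm(20 * 40), 20, 40)
  y <- drop(X[, 5:10] %*% runif(6)) + rnorm(20, sd = 0.2)
  res <- sipls(X, y, g, n_intervals = 2, sizes = 2, max_lv = 5)
  expect_equal(res$best_combo, c(1, 2))
  expect_equal(res$rmsecv_curve, loo_rmsecv(X, y, 5), ignore_attr = TRUE)
})

test_that("the winner attains the minimum of the search table", {
  set.seed(2)
  g <- make_grid(600, 659, 1, dialect = "inclusive_points")
  X <- matrix(rnorm(18 * 60), 18, 60)
  y <- drop(X[, 21:25] %*% runif(5)) + rnorm(18, sd = 0.1)
  res <- sipls(X, y, g, n_intervals = 6, max_lv = 4)
  expect_equal(res$best_rmsecv, min(res$table$rmsecv))
  expect_true(all(res$best_rmsecv <= res$table$rmsecv))
  # selected regions map the winning intervals through the grid
  cols <- ovofresh:::interval_columns(res$partition, res$best_combo)
  expect_true(all(g$values[cols] >= min(res$selected_regions$from) - 1e-9))
  expect_true(all(g$values[cols] <= max(res$selected_regions$to) + 1e-9))
})

test_that("the search is invariant to permuting sample order", {
  set.seed(3)
  g <- make_grid(600, 649, 1, dialect = "inclusive_points")
  X <- matrix(rnorm(15 * 50), 15, 50)
  y <- drop(X[, 11:18] %*% runif(8)) + rnorm(15, sd = 0.2)
  perm <- sample(15)
  a <- sipls(X, y, g, n_intervals = 5, max_lv = 4)
  b <- sipls(X[perm, ], y[perm], g, n_intervals = 5, max_lv = 4)
  expect_equal(a$best_combo, b$best_combo)
  expect_equal(a$best_lv, b$best_lv)
  expect_equal(a$best_rmsecv, b$best_rmsecv, tolerance = 1e-10)
})

test_that("evaluating on the calibration set reproduces the training error", {
  set.seed(4)
  g <- make_grid(600, 639, 1, dialect = "inclusive_points")
  X <- matrix(rnorm(16 * 40), 16, 40)
  y <- drop(X[, 1:6] %*% runif(6)) + rnorm(16, sd = 0.3)
  res <- sipls(X, y, g, n_intervals = 4, max_lv = 3)
  ev <- evaluate_sipls(res, X, y, X, y)
  fit <- pls_fit(X[, res$selected_columns], y, res$best_lv)
  expect_equal(ev$rmsep, sqrt(mean(fit$residuals^2)), tolerance = 1e-10)
  expect_error(sipls(X, rep(1, 16), g, n_intervals = 4), "zero-variance")
})

test_that("prediction through the sipls object uses the selected columns", {
  set.seed(5)
  g <- make_grid(600, 649, 1, dialect = "inclusive_points")
  X <- matrix(rnorm(15 * 50), 15, 50)
  y <- drop(X[, 21:30] %*% runif(10)) + rnorm(15, sd = 0.1)
  res <- sipls(X, y, g, n_intervals = 5, max_lv = 3)
  Xnew <- matrix(rnorm(4 * 50), 4, 50)
  expect_equal(predict(res, Xnew),
               predict(res$model, Xnew[, res$selected_columns]))
  expect_error(predict(res, Xnew[, 1:10]), "full search grid")
})
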