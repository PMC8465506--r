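test_that("well-separated spherical classes are perfectly recovered", {
  set.seed(1)
  sc <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
              matrix(rnorm(20, 10, 0.2), 10, 2))
  lab <- rep(c("a", "b"), each = 10)
  m <- lda_fit(sc, lab)
  expect_equal(predict(m, sc), lab)
  expect_error(lda_fit(sc, rep("a", 20)), "2 classes")
  expect_error(lda_fit(sc, c("a", rep("b", 19))), "at least 2 samples")
})

test_that("identity covariance reduces the discriminant to nearest class mean", {
  set.seed(2)
  mus <- matrix(rnorm(8, sd = 4), 4, 2)
  sc <- mus[rep(1:4, each = 6), ] + matrix(rnorm(48), 24, 2)
  lab <- rep(letters[1:4], each = 6)
  m <- lda_fit(sc, lab, regularization = 0)
  m$pooled_covariance <- diag(2)
  m$chol <- chol(m$pooled_covariance)
  test <- matrix(rnorm(30, sd = 3), 15, 2)
  nearest <- apply(test, 1, function(x)
    m$classes[which.min(colSums((t(m$class_means) - x)^2))])
  expect_equal(predict(m, test), nearest)
})

test_that("exact ties go to the earlier class label", {
  m <- lda_fit(rbind(c(-2, 0.1), c(-2.2, -0.1), c(2, 0.1), c(2.2, -0.1)),
               c("a", "a", "b", "b"), regularization = 0)
  m$pooled_covariance <- diag(2)
  m$chol <- chol(m$pooled_covariance)
  mid <- rbind(colMeans(m$class_means))
  expect_equal(predict(m, mid), "a")
})

test_that("predictions agree with direct evaluation of the Gaussian discriminant", {
  set.seed(3)
  sc <- matrix(rnorm(60, sd = 2), 30, 2)
  lab <- rep(c("x", "y", "z"), each = 10)
  sc[lab == "y", ] <- sc[lab == "y", ] + 3
  sc[lab == "z", 1] <- sc[lab == "z", 1] - 4
  m <- lda_fit(sc, lab)
  Sinv <- solve(m$pooled_covariance)
  test <- matrix(rnorm(20), 10, 2)
  direct <- apply(test, 1, function(x) {
    d <- sapply(seq_along(m$classes), function(k) {
      mu <- m$class_means[k, ]
      drop(x %*% Sinv %*% mu - mu %*% Sinv %*% mu / 2 + log(m$priors[k]))
    })
    m$classes[which.max(d)]
  })
  expect_equal(predict(m, test), direct)
})

test_that("the discriminant matches MASS on a balanced fixture", {
  skip_if_not_installed("MASS")
  set.seed(4)
  sc <- matrix(rnorm(120), 60, 2)
  lab <- rep(c("1", "5", "9"), each = 20)
  sc[lab == "5", ] <- sc[lab == "5", ] + 2.5
  sc[lab == "9", 2] <- sc[lab == "9", 2] + 5
  ours <- predict(lda_fit(sc, lab, regularization = 0), sc)
  ref <- as.character(predict(MASS::lda(sc, grouping = lab))$class)
  expect_equal(ours, ref)
})

test_that("classification is invariant under a consistent affine map", {
  set.seed(5)
  sc <- matrix(rnorm(135), 45, 3)
  lab <- rep(c("a", "b", "c"), each = 15)
  sc[lab == "b", 1] <- sc[lab == "b", 1] + 3
  sc[lab == "c", 2] <- sc[lab == "c", 2] + 3
  test <- matrix(rnorm(30), 10, 3)
  A <- matrix(c(2, 0.5, 0, -0.3, 1.5, 0.2, 0.1, 0, 1), 3, 3)
  b <- c(1, -2, 0.5)
  base <- predict(lda_fit(sc, lab, regularization = 0), test)
  mapped <- predict(lda_fit(sc %*% A + rep(1, 45) %o% b, lab,
                            regularization = 0),
                    test %*% A + rep(1, 10) %o% b)
  expect_equal(mapped, base)
})

test_that("heavy regularization approaches the nearest-mean rule", {
  set.seed(6)
  sc <- matrix(rnorm(80, sd = 2), 40, 2)
  sc[, 2] <- sc[, 2] * 4  # anisotropic pooled covariance
  lab <- rep(c("a", "b"), each = 20)
  sc[lab == "b", ] <- sc[lab == "b", ] + c(3, 12)
  test <- matrix(rnorm(40, sd = 6), 20, 2)
  m_inf <- lda_fit(sc, lab, regularization = 1e8)
  nearest <- apply(test, 1, function(x)
    m_inf$classes[which.min(colSums((t(m_inf$class_means) - x)^2))])
  expect_equal(predict(m_inf, test), nearest)
})

test_that("the qualitative pipeline counts per-day hits on a separable fixture", {
  # classes living on distinct orthogonal axes: 100% train and test
  set.seed(7)
  days <- rep(c(1, 3, 5), each = 9)
  n <- length(days)
  p <- 40
  g <- make_grid(600, 600 + p - 1, 1, dialect = "inclusive_points")
  X <- matrix(rnorm(n * p, sd = 0.01), n, p) + 1
  for (i in seq_len(n)) X[i, 5 + 10 * (days[i] - 1) / 2] <- 3
  s <- spectra_set(X, g, sprintf("e%02d", 1:n),
                   data.frame(storage_day = days, temp_group = "25C",
                              replicate = rep(1:9, 3)))
  rep <- qualify_pipeline(s, preprocess_config("none"), n_pcs = 3)
  expect_equal(rep$train_accuracy, 100)
  expect_equal(rep$test_accuracy, 100)
  expect_equal(rep$per_day$train_total, rep(6, 3))
  expect_equal(rep$per_day$test_total, rep(3, 3))
  expect_equal(sum(diag(rep$confusion)), sum(rep$per_day$test_total))
  expect_equal(unname(rowSums(rep$confusion)), rep$per_day$test_total)
})
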