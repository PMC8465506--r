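test_that("SNV standardizes to mean 0, sd 1 and is scatter-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50)
  z <- (x - mean(x)) / sd(x)
  expect_equal(snv(z), z)
  # multiplicative gain and additive offset are removed exactly
  for (i in 1:5) {
    x <- rnorm(40, mean = 2)
    a <- runif(1, 0.2, 5)
    b <- rnorm(1, sd = 3)
    expect_equal(snv(a * x + b), snv(x), tolerance = 1e-12)
  }
  expect_error(snv(c(5, 5, 5), sample_id = "egg7"), "egg7")
  expect_error(snv(3), "at least 2")
})

test_that("MSC inverts affine scatter against the reference", {
  set.seed(2)
  ref <- rnorm(30, mean = 1.5)
  expect_equal(drop(msc(ref, ref)), ref)
  expect_equal(drop(msc(2 * ref + 3, ref)), ref)
  # idempotence with the same reference
  X <- rbind(1.3 * ref - 0.2, 0.8 * ref + 1, ref + rnorm(30, sd = 0.01))
  once <- msc(X, ref)
  expect_equal(msc(once, ref), once, tolerance = 1e-10)
  expect_error(msc(X, rep(1, 30)), "zero-variance")
})

test_that("Savitzky-Golay derivatives are exact for low-order polynomials", {
  g <- make_grid(550, 700, 0.5)
  lam <- g$values
  const <- rep(2.5, length(lam))
  expect_equal(sg_derivative(const, 1, g$step), rep(0, length(lam)))
  ramp <- 0.03 * lam
  d1 <- sg_derivative(ramp, 1, g$step)
  expect_equal(d1, rep(0.03, length(lam)), tolerance = 1e-8)
  quad <- 2e-4 * lam^2
  d2 <- sg_derivative(quad, 2, g$step, polyorder = 2)
  inner <- 8:(length(lam) - 7)
  expect_equal(d2[inner], rep(4e-4, length(inner)), tolerance = 1e-6)
  expect_error(sg_derivative(ramp[1:10], 1, g$step, window = 15), "window")
})

test_that("the first derivative removes row-wise constant offsets", {
  set.seed(3)
  X <- matrix(rnorm(5 * 60, mean = 1), 5, 60)
  offs <- matrix(rnorm(5, sd = 2), 5, 60)
  expect_equal(sg_derivative(X + offs, 1, 0.5), sg_derivative(X, 1, 0.5),
               tolerance = 1e-10)
})

test_that("row-wise pretreatments commute with sample permutation", {
  s <- toy_spectra(n = 6, p = 40, seed = 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  for (m in c("snv", "deriv1")) {
    cfg <- preprocess_config(m, sg_window = 11)
    a <- apply_preprocess(s, cfg)$absorbance[perm, ]
    b <- apply_preprocess(s[perm], cfg)$absorbance
    expect_equal(unname(a), unname(b))
  }
})

test_that("the MSC reference comes from calibration rows only", {
  s <- toy_spectra(n = 6, p = 25, seed = 5)
  cal <- 1:4
  cfg <- preprocess_config("msc")
  got <- apply_preprocess(s, cfg, calibration_indices = cal)$absorbance
  ref <- colMeans(s$absorbance[cal, ])
  expect_equal(unname(got), unname(msc(s$absorbance, ref)))
  # changing a prediction row must not change the treatment of others
  s2 <- s
  s2$absorbance[6, ] <- s2$absorbance[6, ] + 5
  got2 <- apply_preprocess(s2, cfg, calibration_indices = cal)$absorbance
  expect_equal(got2[1:5, ], got[1:5, ])
  expect_error(apply_preprocess(s, cfg), "calibration_indices")
})

test_that("MSC maps an affine family of one shape onto a single spectrum", {
  set.seed(6)
  shape <- 1 + exp(-0.5 * ((1:30 - 15) / 5)^2)
  X <- t(sapply(1:5, function(i) runif(1, 0.5, 2) * shape + rnorm(1)))
  g <- make_grid(600, 629, 1, dialect = "inclusive_points")
  s <- spectra_set(X, g, paste0("e", 1:5),
                   data.frame(storage_day = 1, temp_group = "25C",
                              replicate = 1:5))
  out <- apply_preprocess(s, preprocess_config("msc"),
                          calibration_indices = 1:5)$absorbance
  for (i in 2:5) expect_equal(unname(out[i, ]), unname(out[1, ]),
                              tolerance = 1e-8)
})

test_that("a 'none' configuration is the identity and bad configs are rejected", {
  s <- toy_spectra()
  expect_equal(apply_preprocess(s, preprocess_config("none"))$absorbance,
               s$absorbance)
  expect_error(preprocess_config(sg_window = 14), "odd")
  expect_error(preprocess_config(sg_window = 3, sg_polyorder = 2), "at least")
  expect_error(preprocess_config("deriv2", sg_polyorder = 1), "polyorder")
})
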