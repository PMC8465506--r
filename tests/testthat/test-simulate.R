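small_cfg <- function(...) {
  sim_config(grid = make_grid(550, 985, 4.35), eggs_per_day = 3, ...)
}

test_that("the default design produces 105 samples on the instrument grid", {
  cfg <- sim_config(grid = thin_grid())
  dat <- generate_dataset(cfg)
  expect_equal(dim(dat$spectra), c(105, 399))
  expect_equal(as.vector(table(dat$spectra$metadata$storage_day)),
               rep(15, 7))
  expect_equal(nrow(dat$destructive), 105)
})

test_that("one seed governs everything and the caller's RNG is untouched", {
  cfg <- small_cfg(seed = 99)
  set.seed(123)
  before <- .Random.seed
  a <- generate_dataset(cfg)
  expect_identical(.Random.seed, before)
  b <- generate_dataset(cfg)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$destructive, b$destructive)
  expect_identical(a$truth$indices, b$truth$indices)
  d <- generate_dataset(small_cfg(seed = 100))
  expect_false(identical(a$spectra$absorbance, d$spectra$absorbance))
})

test_that("the destructive table back-solves to the drawn indices", {
  dat <- generate_dataset(small_cfg(seed = 3))
  derived <- freshness_indices(dat$destructive)
  expect_equal(derived$haugh_unit, dat$truth$indices$haugh_unit,
               tolerance = 1e-9)
  expect_equal(derived$yolk_index, dat$truth$indices$yolk_index,
               tolerance = 1e-9)
  expect_equal(derived$weight_loss, dat$truth$indices$weight_loss,
               tolerance = 1e-9)
})

test_that("zero index noise collapses draws to the trajectory means", {
  for (regime in c("A_25C", "B_4C")) {
    traj <- index_trajectory(regime)
    set.seed(1)
    for (i in c(1, 4, 7)) {
      idx <- simulate_indices(traj$day[i], regime, index_noise_scale = 0)
      expect_equal(idx$haugh_unit, traj$hu_mean[i])
      expect_equal(idx$yolk_index, traj$yi_mean[i])
      expect_equal(idx$weight_loss, traj$wr_mean[i])
      expect_equal(idx$latent$haugh_unit, traj$hu_mean[i])
    }
  }
  expect_error(simulate_indices(2, "A_25C"), "outside the storage design")
})

test_that("index draws match the trajectory moments in distribution", {
  set.seed(10)
  traj <- index_trajectory("A_25C")
  hu <- replicate(4000, simulate_indices(1, "A_25C")$haugh_unit)
  expect_equal(mean(hu), traj$hu_mean[1], tolerance = 0.2)
  expect_equal(sd(hu), traj$hu_sd[1], tolerance = 0.15)
  # the latent/measured split preserves the total sd
  wr <- replicate(4000, simulate_indices(13, "A_25C")$weight_loss)
  expect_equal(sd(wr), traj$wr_sd[7], tolerance = 0.05)
})

test_that("with couplings and noise off every spectrum is the same baseline", {
  b <- default_bands()
  b$c_hu <- b$c_yi <- b$c_wr <- 0
  nb <- default_nuisance_bands()
  nb$amp_sd <- 0
  cfg <- small_cfg(bands = b, nuisance_bands = nb, scatter_sd_mult = 0,
                   scatter_sd_add = 0, noise_sd = 0)
  dat <- generate_dataset(cfg)
  X <- dat$spectra$absorbance
  expect_equal(max(apply(X, 2, function(col) diff(range(col)))), 0)
})

test_that("band amplitude responds linearly to the coupling coefficient", {
  idx <- list(haugh_unit = 80, yolk_index = 0.3, weight_loss = 2.5)
  grid <- thin_grid()
  mk <- function(cwr) {
    b <- default_bands()
    b$c_wr[2] <- cwr
    nb <- default_nuisance_bands()
    nb$amp_sd <- 0
    sim_config(grid = grid, bands = b, nuisance_bands = nb,
               scatter_sd_mult = 0, scatter_sd_add = 0, noise_sd = 0)
  }
  idx2 <- list(haugh_unit = 80, yolk_index = 0.3, weight_loss = 0.5)
  d1 <- simulate_spectrum(idx, mk(0.1))$spectrum -
    simulate_spectrum(idx2, mk(0.1))$spectrum
  d2 <- simulate_spectrum(idx, mk(0.2))$spectrum -
    simulate_spectrum(idx2, mk(0.2))$spectrum
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  # the difference is confined to the weight-loss band at 760 nm
  # (distant channels see only the far Gaussian tail)
  lam <- grid$values
  expect_lt(max(abs(d1[abs(lam - 760) > 120])), 1e-6)
  expect_gt(max(abs(d1[abs(lam - 760) < 20])), 0.01)
})

test_that("with scatter and noise off, inter-sample differences are band-driven", {
  nb <- default_nuisance_bands()
  nb$amp_sd <- 0
  cfg <- small_cfg(nuisance_bands = nb, scatter_sd_mult = 0,
                   scatter_sd_add = 0, noise_sd = 0, seed = 8)
  dat <- generate_dataset(cfg)
  lam <- cfg$grid$values
  b <- default_bands()
  off_band <- apply(abs(outer(lam, b$center, "-")) > 4 * rep(b$width,
                    each = length(lam)), 1, all)
  X <- dat$spectra$absorbance
  spread <- apply(X, 2, function(col) diff(range(col)))
  # band channels vary across eggs; off-band channels only via distant
  # Gaussian tails
  expect_lt(max(spread[off_band]), 0.01)
  expect_gt(max(spread[!off_band]), 0.1)
})

test_that("the informative mask covers the planted bands and nothing else", {
  cfg <- small_cfg()
  dat <- generate_dataset(cfg)
  mask <- dat$truth$informative_mask
  expect_true(any(mask))
  lam <- cfg$grid$values
  b <- default_bands()
  inside <- rowSums(sapply(seq_len(nrow(b)), function(i)
    abs(lam - b$center[i]) <= 2 * b$width[i])) > 0
  expect_equal(mask, inside)
})

test_that("configurations are validated", {
  expect_error(sim_config(eggs_per_day = 1), "eggs_per_day")
  expect_error(sim_config(days = c(1, 2)), "subset")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  b <- default_bands()
  b$center[1] <- 100
  expect_error(sim_config(bands = b), "inside the grid")
  expect_error(sim_config(bio_frac = c(hu = 2, yi = 0.5, wr = 1)),
               "bio_frac")
})
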