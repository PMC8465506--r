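#' Reference freshness-index trajectories for the two storage regimes
#'
#' Per-day means and standard deviations of the Haugh unit, yolk index and
#' weight-loss rate for eggs stored 1-13 days at room temperature (25 C)
#' or refrigerated (4 C). These trajectories are the generative means of
#' the synthetic-data module: at 25 C the Haugh unit and yolk index fall
#' monotonically and weight loss climbs nearly thirty-fold; at 4 C the
#' Haugh unit and yolk index drift irregularly while weight loss grows
#' slowly. The contrast is what makes room-temperature storage days
#' discriminable from spectra and refrigerated ones not.
#'
#' @param regime `"A_25C"` or `"B_4C"`.
#' @return data.frame with columns `day`, `hu_mean`, `hu_sd`, `yi_mean`,
#'   `yi_sd`, `wr_mean`, `wr_sd`.
#' @export
index_trajectory <- function(regime = c("A_25C", "B_4C")) {
  regime <- match.arg(regime)
  day <- c(1, 3, 5, 7, 9, 11, 13)
  if (regime == "A_25C")
    data.frame(
      day = day,
      hu_mean = c(84.94, 81.75, 80.01, 79.35, 70.95, 65.96, 59.19),
      hu_sd   = c(4.05, 4.59, 1.85, 4.09, 5.11, 5.62, 1.87),
      yi_mean = c(0.36, 0.32, 0.32, 0.28, 0.26, 0.24, 0.20),
      yi_sd   = c(0.041, 0.11, 0.042, 0.038, 0.11, 0.032, 0.031),
      wr_mean = c(0.117, 0.637, 0.954, 1.526, 2.068, 2.760, 3.286),
      wr_sd   = c(0.0246, 0.055, 0.132, 0.281, 0.299, 0.446, 0.467))
  else
    data.frame(
      day = day,
      hu_mean = c(85.89, 89.78, 92.75, 92.63, 94.57, 94.65, 92.05),
      hu_sd   = c(4.73, 2.65, 4.17, 2.76, 3.25, 2.98, 2.56),
      yi_mean = c(0.42, 0.443, 0.433, 0.443, 0.437, 0.449, 0.430),
      yi_sd   = c(0.027, 0.027, 0.025, 0.02, 0.034, 0.02, 0.019),
      wr_mean = c(0.173, 0.325, 0.469, 0.66, 1.04, 1.22, 1.52),
      wr_sd   = c(0.043, 0.066, 0.054, 0.18, 0.14, 0.17, 0.20))
}

# Fixed absolute standardization of the indices for spectral coupling:
# the spectrum responds to the egg's chemistry, not to which regime the
# egg came from, so one scale (the room-temperature trajectory's spread)
# is used for both regimes. Weight loss spans nearly thirty-fold and its
# within-day spread grows with its level, so it enters the coupling on
# the log scale (multiplicative quantity, Beer-Lambert-consistent);
# Haugh unit and yolk index enter linearly. Frozen constants derived
# once from the index_trajectory("A_25C") per-day means.
index_scale_constants <- function() {
  list(hu = c(center = 74.592857, scale = 9.445533),
       yi = c(center = 0.282857, scale = 0.054685),
       log_wr = c(center = 0.101496, scale = 1.146704))
}

#' Default absorption bands coupling freshness indices to the spectrum
#'
#' Three Gaussian bands inside the informative regions of the
#' visible-NIR transmittance axis: 665 nm and 760 nm in the 650-777 nm
#' window, 930 nm in the 899-965 nm window. Couplings (absorbance per
#' standardized index unit) route the Haugh unit through the 665 nm band
#' (C-H/O-H), the weight-loss rate through the 760 nm band (O-H) and the
#' yolk index through the 930 nm band (N-H/O-H). The weight-loss
#' coupling acts on the log scale, see [sim_config()].
#'
#' @return data.frame with `center`, `width` (Gaussian sigma, nm),
#'   `base_amp` and coupling columns `c_hu`, `c_yi`, `c_wr`.
#' @export
default_bands <- function() {
  data.frame(
    center   = c(665, 760, 930),
    width    = c(15, 20, 25),
    base_amp = c(0.40, 0.45, 0.40),
    c_hu     = c(0.200, 0.000, 0.000),
    c_yi     = c(0.000, 0.000, 0.200),
    c_wr     = c(0.000, 0.120, 0.000))
}

#' Default interfering-absorber (nuisance) bands
#'
#' Twelve Gaussian bands whose amplitudes vary egg-to-egg independently
#' of freshness: the structured shell-pigment absorption of brown eggs
#' (protoporphyrin IX and carotenoid features crowd the 550-630 nm end)
#' and minor composition variability between the freshness-informative
#' regions. Their joint rank is what a full-spectrum calibration has to
#' spend latent variables on; none of them overlaps the informative
#' bands of [default_bands()]. See the `nuisance_bands` argument of
#' [sim_config()].
#'
#' @return data.frame with `center`, `width` (Gaussian sigma, nm) and
#'   `amp_sd` (per-egg amplitude sd, AU).
#' @export
default_nuisance_bands <- function() {
  data.frame(
    center = c(558, 572, 586, 600, 614, 628, 710, 808, 825, 842, 860, 876),
    width  = c(8, 10, 10, 12, 10, 8, 10, 10, 10, 10, 12, 10),
    amp_sd = c(0.08, 0.12, 0.10, 0.10, 0.10, 0.08, 0.07, 0.08, 0.07,
               0.08, 0.08, 0.07))
}

#' Configuration of the synthetic spectra generator
#'
#' Defines the study conditions the generator emulates: 15 eggs per
#' storage day over 7 storage days (105 samples per regime), a 550-985 nm
#' transmittance grid at a 0.21 nm increment (2071 variables), Gaussian
#' absorption bands linearly coupled to the freshness indices, and the
#' scatter-artifact family (per-sample multiplicative gain and additive
#' offset) that SNV / MSC / derivative pretreatments are designed to
#' remove, plus white measurement noise.
#'
#' @param regime `"A_25C"` or `"B_4C"`.
#' @param days storage days simulated (default the 1-13 odd-day design).
#' @param eggs_per_day eggs per day subgroup (default 15).
#' @param grid spectral axis (default the 2071-point transmittance grid).
#' @param bands band table as in [default_bands()].
#' @param scatter_sd_mult sdlog of the lognormal multiplicative gain
#'   (default 0.04).
#' @param scatter_sd_add sd of the additive offset in AU (default 0.05).
#' @param noise_sd per-channel white noise sd in AU (default 0.005) at
#'   the grid center.
#' @param edge_noise_mult detector-edge noise inflation: the white-noise
#'   sd follows `noise_sd * (1 + edge_noise_mult * u^6)` with `u` the
#'   axis position scaled to \[-1, 1\], emulating the sensitivity
#'   roll-off of a CCD spectrometer at the ends of its range (default
#'   40, i.e. edge channels are about 41 times noisier than central
#'   ones). This is what makes wavelength-interval selection pay off:
#'   full-spectrum calibrations drag the noisy edges along.
#' @param index_noise_scale multiplier on the trajectory sds when drawing
#'   indices (1 = the reference within-day spread; 0 = deterministic
#'   means).
#' @param nuisance_bands data.frame of interfering absorbers with
#'   `center`, `width` (nm) and `amp_sd`: Gaussian bands whose amplitude
#'   varies egg-to-egg (normal, mean 0) independently of freshness —
#'   shell pigment (protoporphyrin around 575/640 nm), carotenoids and
#'   sample-to-sample water-band shifts. They model the freshness-
#'   irrelevant spectral variability of real eggs: a full-spectrum
#'   calibration must spend latent variables deflating them, whereas
#'   interval selection can avoid most of them spatially and a
#'   discriminant classifier learns them in its within-class covariance.
#' @param bio_frac named vector: the fraction of each index's within-day
#'   standard deviation attributed to real egg-to-egg (biological)
#'   variation, the rest being destructive-measurement error. The
#'   spectrum reflects the egg itself, so bands couple to the latent
#'   biological value; the destructive table reports the measured value
#'   (latent plus measurement error, total sd equal to the trajectory
#'   sd). Defaults: weight loss 1 (a 1 mg balance on a 60 g egg is
#'   essentially exact), Haugh unit 0.4 and yolk index 0.5 (albumen
#'   height gauges and hand calipers are the dominant error source).
#' @param seed integer seed governing every draw of one generated dataset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(regime = c("A_25C", "B_4C"),
                       days = c(1, 3, 5, 7, 9, 11, 13),
                       eggs_per_day = 15,
                       grid = make_grid(550, 985, 0.21),
                       bands = default_bands(),
                       scatter_sd_mult = 0.06,
                       scatter_sd_add = 0.15,
                       noise_sd = 0.005,
                       edge_noise_mult = 40,
                       nuisance_bands = default_nuisance_bands(),
                       index_noise_scale = 1,
                       bio_frac = c(hu = 0.4, yi = 0.5, wr = 1),
                       seed = 1L) {
  regime <- match.arg(regime)
  validate_grid(grid)
  if (eggs_per_day < 2) stop("eggs_per_day must be >= 2")
  if (any(c(scatter_sd_mult, scatter_sd_add, noise_sd, edge_noise_mult,
            index_noise_scale) < 0))
    stop("noise parameters must be >= 0")
  rng <- range(grid$values)
  if (any(bands$center < rng[1] | bands$center > rng[2]))
    stop("band centers must lie inside the grid")
  traj <- index_trajectory(regime)
  if (!all(days %in% traj$day))
    stop("days must be a subset of the designed storage days ",
         paste(traj$day, collapse = ", "))
  if (!all(c("hu", "yi", "wr") %in% names(bio_frac)) ||
      any(bio_frac < 0 | bio_frac > 1))
    stop("bio_frac must name hu, yi, wr with values in [0, 1]")
  structure(list(regime = regime, days = days,
                 eggs_per_day = as.integer(eggs_per_day), grid = grid,
                 bands = bands, scatter_sd_mult = scatter_sd_mult,
                 scatter_sd_add = scatter_sd_add, noise_sd = noise_sd,
                 edge_noise_mult = edge_noise_mult,
                 nuisance_bands = nuisance_bands,
                 index_noise_scale = index_noise_scale,
                 bio_frac = bio_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw freshness indices for one egg
#'
#' Normal draws around the regime's per-day trajectory means with the
#' trajectory sds (scaled by `index_noise_scale`); weight loss is
#' truncated at zero (yolk index just above it). The within-day spread
#' is decomposed into a latent biological component (fraction `bio_frac`
#' of the sd, the egg's real state, which drives the spectrum) and an
#' independent destructive-measurement error (the remainder in
#' quadrature), so the returned measured values still have the full
#' trajectory sd. With the noise scale at zero both components collapse
#' to the trajectory means exactly.
#'
#' @param day storage day, one of the designed days.
#' @param regime `"A_25C"` or `"B_4C"`.
#' @param index_noise_scale sd multiplier (default 1).
#' @param bio_frac biological fraction per index, see [sim_config()].
#' @return List with the measured `haugh_unit`, `yolk_index`,
#'   `weight_loss` and a `latent` sublist holding the biological values.
#' @export
simulate_indices <- function(day, regime = c("A_25C", "B_4C"),
                             index_noise_scale = 1,
                             bio_frac = c(hu = 0.4, yi = 0.5, wr = 1)) {
  regime <- match.arg(regime)
  traj <- index_trajectory(regime)
  i <- match(day, traj$day)
  if (is.na(i)) stop("day ", day, " is outside the storage design")
  s <- index_noise_scale
  draw <- function(mu, sdv, f, lower = -Inf) {
    lat <- max(lower, rnorm(1, mu, s * f * sdv))
    c(lat, max(lower, lat + rnorm(1, 0, s * sqrt(1 - f^2) * sdv)))
  }
  hu <- draw(traj$hu_mean[i], traj$hu_sd[i], bio_frac[["hu"]])
  yi <- draw(traj$yi_mean[i], traj$yi_sd[i], bio_frac[["yi"]], lower = 1e-3)
  wr <- draw(traj$wr_mean[i], traj$wr_sd[i], bio_frac[["wr"]], lower = 1e-4)
  list(haugh_unit = hu[2], yolk_index = yi[2], weight_loss = wr[2],
       latent = list(haugh_unit = hu[1], yolk_index = yi[1],
                     weight_loss = wr[1]))
}

# smooth instrument baseline, in absorbance units
sim_baseline <- function(lambda) {
  1.1 + 0.35 * exp(-0.5 * ((lambda - 585) / 70)^2) +
    0.25 * (lambda - 550) / 435
}

standardized_indices <- function(idx) {
  k <- index_scale_constants()
  c(hu = (idx$haugh_unit - k$hu[["center"]]) / k$hu[["scale"]],
    yi = (idx$yolk_index - k$yi[["center"]]) / k$yi[["scale"]],
    wr = (log(max(idx$weight_loss, 1e-4)) - k$log_wr[["center"]]) /
      k$log_wr[["scale"]])
}

#' Simulate one diffuse-transmittance spectrum
#'
#' `absorbance(lambda) = baseline(lambda) + sum_b amp_b * exp(-((lambda -
#' center_b)^2) / (2 width_b^2))`, with `amp_b = base_amp_b + c_hu*z_HU +
#' c_yi*z_YI + c_wr*z_WR` (standardized indices on the fixed absolute
#' scale; weight loss enters through its logarithm), then multiplied by
#' a lognormal gain, shifted by a normal offset and degraded by white
#' noise. The bands couple to the latent biological index values when
#' `idx` carries them (the spectrum measures the egg, not the caliper),
#' and to the plain values otherwise.
#'
#' @param idx indices as from [simulate_indices()].
#' @param cfg a [sim_config()].
#' @return List with `spectrum` (length of the grid), `scatter_mult`,
#'   `scatter_add`.
#' @export
simulate_spectrum <- function(idx, cfg) {
  lambda <- cfg$grid$values
  z <- standardized_indices(if (is.null(idx$latent)) idx else idx$latent)
  clean <- sim_baseline(lambda)
  for (b in seq_len(nrow(cfg$bands))) {
    bb <- cfg$bands[b, ]
    amp <- bb$base_amp + bb$c_hu * z["hu"] + bb$c_yi * z["yi"] +
      bb$c_wr * z["wr"]
    clean <- clean + amp * exp(-0.5 * ((lambda - bb$center) / bb$width)^2)
  }
  nb <- cfg$nuisance_bands
  for (b in seq_len(NROW(nb))) {
    a <- rnorm(1, 0, nb$amp_sd[b])
    clean <- clean + a * exp(-0.5 * ((lambda - nb$center[b]) / nb$width[b])^2)
  }
  mult <- if (cfg$scatter_sd_mult > 0) rlnorm(1, 0, cfg$scatter_sd_mult) else 1
  add <- if (cfg$scatter_sd_add > 0) rnorm(1, 0, cfg$scatter_sd_add) else 0
  noise <- if (cfg$noise_sd > 0) {
    u <- 2 * (lambda - mean(range(lambda))) / diff(range(lambda))
    rnorm(length(lambda), 0,
          cfg$noise_sd * (1 + cfg$edge_noise_mult * u^6))
  } else 0
  list(spectrum = clean * mult + add + noise,
       scatter_mult = mult, scatter_add = add)
}

#' Generate a complete synthetic dataset
#'
#' Draws `eggs_per_day x length(days)` eggs, simulates their freshness
#' indices and spectra, and back-solves a destructive-measurement table
#' consistent with the drawn indices: the original egg mass is drawn
#' around 60 g, the stored mass follows from the weight loss, the albumen
#' height is solved from the Haugh unit at that mass, and the yolk height
#' follows from the yolk index at a drawn yolk diameter — so applying the
#' index formulas to the destructive table reproduces the drawn values
#' exactly. All randomness flows from `cfg$seed`; the caller's RNG state
#' is left untouched.
#'
#' @param cfg a [sim_config()].
#' @return List with `spectra` (a [spectra_set()]), `destructive`
#'   (data.frame of masses and heights), `truth` (drawn indices, scatter
#'   parameters, and the informative-variable mask covering the planted
#'   bands at +/- 2 sigma).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  grp <- if (cfg$regime == "A_25C") "25C" else "4C"
  n <- cfg$eggs_per_day * length(cfg$days)
  lambda <- cfg$grid$values
  X <- matrix(NA_real_, n, length(lambda))
  meta <- data.frame(storage_day = integer(n), temp_group = character(n),
                     replicate = integer(n))
  truth <- data.frame(haugh_unit = numeric(n), yolk_index = numeric(n),
                      weight_loss = numeric(n), latent_haugh_unit = numeric(n),
                      latent_yolk_index = numeric(n),
                      latent_weight_loss = numeric(n),
                      scatter_mult = numeric(n), scatter_add = numeric(n))
  dest <- data.frame(mass_original_g = numeric(n), mass_current_g = numeric(n),
                     albumen_height_mm = numeric(n), yolk_height_mm = numeric(n),
                     yolk_diameter_mm = numeric(n))
  i <- 0
  for (day in cfg$days) for (rep_ in seq_len(cfg$eggs_per_day)) {
    i <- i + 1
    idx <- simulate_indices(day, cfg$regime, cfg$index_noise_scale,
                            cfg$bio_frac)
    sp <- simulate_spectrum(idx, cfg)
    X[i, ] <- sp$spectrum
    meta[i, ] <- list(day, grp, rep_)
    truth[i, ] <- list(idx$haugh_unit, idx$yolk_index, idx$weight_loss,
                       idx$latent$haugh_unit, idx$latent$yolk_index,
                       idx$latent$weight_loss,
                       sp$scatter_mult, sp$scatter_add)
    w_org <- rnorm(1, 60, 2.5)
    w_cur <- w_org * (1 - idx$weight_loss / 100)
    d_yolk <- rnorm(1, 40, 1.2)
    dest[i, ] <- list(w_org, w_cur,
                      albumen_height_for(idx$haugh_unit, w_cur),
                      idx$yolk_index * d_yolk, d_yolk)
  }
  ids <- sprintf("%s_d%02d_r%02d", grp, meta$storage_day, meta$replicate)
  mask <- rep(FALSE, length(lambda))
  for (b in seq_len(nrow(cfg$bands)))
    mask <- mask | abs(lambda - cfg$bands$center[b]) <= 2 * cfg$bands$width[b]
  list(spectra = spectra_set(X, cfg$grid, ids, meta),
       destructive = cbind(sample_id = ids, dest),
       truth = list(indices = cbind(sample_id = ids, truth),
                    informative_mask = mask,
                    config = cfg))
}
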