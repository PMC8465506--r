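#' Weight-loss rate of a stored egg
#'
#' Percent mass lost relative to the fresh egg,
#' `100 * (w_org - w_tst) / w_org`. Mass escapes as water vapour and CO2
#' through the shell pores, so the rate can only grow with storage time.
#'
#' @param w_org original (fresh) mass in g, positive.
#' @param w_tst mass after storage in g, `0 < w_tst <= w_org`.
#' @return Weight loss in percent. Vectorized.
#' @export
weight_loss <- function(w_org, w_tst) {
  if (any(w_org <= 0)) stop("original mass must be positive")
  if (any(w_tst > w_org))
    stop("stored mass exceeds original mass (evaporation cannot add mass)")
  100 * (w_org - w_tst) / w_org
}

#' Yolk index
#'
#' Ratio of yolk height to yolk diameter; the yolk flattens as the
#' vitelline membrane weakens, so the index decreases with egg age.
#'
#' @param yolk_height,yolk_diameter in mm, both positive.
#' @return `yolk_height / yolk_diameter`. Vectorized.
#' @export
yolk_index <- function(yolk_height, yolk_diameter) {
  if (any(yolk_height <= 0) || any(yolk_diameter <= 0))
    stop("yolk height and diameter must be positive")
  yolk_height / yolk_diameter
}

#' Haugh unit
#'
#' The standard albumen-quality freshness score,
#' `HU = 100 * log10(h + 7.57 - 1.7 * m^0.37)`, from thick-albumen height
#' `h` (mm, averaged over three measurements 10 mm from the yolk, see
#' [mean_albumen_height()]) and egg mass `m` (g). Higher is fresher.
#'
#' @param albumen_height thick albumen height h in mm.
#' @param egg_mass egg mass m in g, positive.
#' @return The Haugh unit. Vectorized.
#' @export
haugh_unit <- function(albumen_height, egg_mass) {
  if (any(egg_mass <= 0)) stop("egg mass must be positive")
  arg <- albumen_height + 7.57 - 1.7 * egg_mass^0.37
  if (any(arg <= 0))
    stop(sprintf(
      "non-positive log argument (h = %.4g, m = %.4g gives %.4g)",
      albumen_height[which(arg <= 0)[1]], egg_mass[which(arg <= 0)[1]],
      min(arg)))
  100 * log10(arg)
}

#' Invert the Haugh unit for albumen height
#'
#' Solves `HU = 100 * log10(h + 7.57 - 1.7 * m^0.37)` for `h` at a given
#' egg mass; used by the synthetic-data generator to back-solve consistent
#' destructive measurements from drawn index values.
#'
#' @param hu Haugh unit.
#' @param egg_mass egg mass in g.
#' @return Albumen height h in mm.
#' @export
albumen_height_for <- function(hu, egg_mass) {
  10^(hu / 100) - 7.57 + 1.7 * egg_mass^0.37
}

#' Mean thick-albumen height from the three standard measurements
#' @param h1,h2,h3 albumen heights (mm) measured 10 mm from the yolk.
#' @return Their arithmetic mean. Vectorized.
#' @export
mean_albumen_height <- function(h1, h2, h3) (h1 + h2 + h3) / 3

#' USDA-style grade from the Haugh unit
#'
#' Grade AA/A boundary at HU = 72, boundary inclusive (HU of exactly 72 is
#' graded AA).
#'
#' @param hu finite Haugh unit value(s).
#' @return Character vector of `"AA"` / `"A"`.
#' @export
egg_grade <- function(hu) {
  if (any(!is.finite(hu))) stop("HU must be finite")
  ifelse(hu >= 72, "AA", "A")
}

#' Freshness indices from a table of destructive measurements
#'
#' @param records data.frame with columns `mass_original_g`,
#'   `mass_current_g`, `albumen_height_mm`, `yolk_height_mm`,
#'   `yolk_diameter_mm` (and optionally `sample_id`, `storage_day`,
#'   `temp_group` which are carried through).
#' @return The input with columns `haugh_unit`, `yolk_index`,
#'   `weight_loss` and `grade` appended.
#' @export
freshness_indices <- function(records) {
  records <- as.data.frame(records)
  hu <- haugh_unit(records$albumen_height_mm, records$mass_current_g)
  cbind(records,
        haugh_unit = hu,
        yolk_index = yolk_index(records$yolk_height_mm,
                                records$yolk_diameter_mm),
        weight_loss = weight_loss(records$mass_original_g,
                                  records$mass_current_g),
        grade = egg_grade(hu))
}

#' Per-day summary of freshness indices
#'
#' Mean and standard deviation of HU, yolk index and weight loss per
#' (storage day, temperature group) cell, plus the squared Pearson
#' correlation of the per-day group means against storage day for each
#' index within each group — a linear-trend strength summary. For the
#' room-temperature weight-loss trajectory of the emulated study this R^2
#' is 0.99. When a group's per-day means are constant the correlation is
#' undefined and reported as `NA`.
#'
#' @param indices a data.frame as returned by [freshness_indices()], with
#'   `storage_day` and `temp_group` columns; at least 2 records per cell.
#' @return List with `summary` (one row per day x group: n and mean/sd of
#'   each index) and `trend_r2` (one row per group x index).
#' @export
index_table <- function(indices) {
  need <- c("storage_day", "temp_group", "haugh_unit", "yolk_index",
            "weight_loss")
  stopifnot(all(need %in% names(indices)))
  cols <- c("haugh_unit", "yolk_index", "weight_loss")
  cells <- split(indices, list(indices$temp_group, indices$storage_day),
                 drop = TRUE)
  if (any(vapply(cells, nrow, 0L) < 2))
    stop("each (day, group) cell needs at least 2 records")
  summ <- do.call(rbind, lapply(cells, function(cell) {
    out <- data.frame(temp_group = cell$temp_group[1],
                      storage_day = cell$storage_day[1], n = nrow(cell))
    for (v in cols) {
      out[[paste0(v, "_mean")]] <- mean(cell[[v]])
      out[[paste0(v, "_sd")]] <- sd(cell[[v]])
    }
    out
  }))
  summ <- summ[order(summ$temp_group, summ$storage_day), ]
  rownames(summ) <- NULL
  r2 <- do.call(rbind, lapply(split(summ, summ$temp_group), function(g) {
    data.frame(temp_group = g$temp_group[1], index = cols,
               r2 = vapply(cols, function(v) {
                 m <- g[[paste0(v, "_mean")]]
                 if (sd(m) == 0 || sd(g$storage_day) == 0) NA_real_
                 else cor(g$storage_day, m)^2
               }, 0))
  }))
  rownames(r2) <- NULL
  list(summary = summ, trend_r2 = r2)
}

#' Overall accuracy from per-class counts
#'
#' Pools per-class (correct, total) counts into an overall percentage,
#' `100 * sum(correct) / sum(total)`, reported to one decimal
#' (round-half-away-from-zero).
#'
#' @param correct,total integer vectors of per-class correct and total
#'   counts; `total > 0`.
#' @return One-decimal percentage.
#' @export
accuracy_from_counts <- function(correct, total) {
  if (!length(total) || any(total <= 0)) stop("totals must be positive")
  if (length(correct) != length(total)) stop("length mismatch")
  if (any(correct > total)) stop("correct exceeds total")
  pct <- 100 * sum(correct) / sum(total)
  floor(pct * 10 + 0.5) / 10
}
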