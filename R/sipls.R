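#' Equidistant partition of spectral variables into intervals
#'
#' Splits `n_variables` consecutive variables into `n_intervals` contiguous
#' intervals whose lengths differ by at most one. With remainder
#' `r = n_variables %% n_intervals`, the first `r` intervals get the extra
#' variable (remainder-first rule, fixed for reproducibility). A 2071-point
#' grid in 25 intervals gives 21 intervals of 83 variables and 4 of 82.
#'
#' @param n_variables,n_intervals integers,
#'   `2 <= n_intervals <= n_variables`.
#' @return An object of class `interval_partition`: data.frame with
#'   1-based inclusive `start`, `end` and `length` per interval.
#' @export
partition_intervals <- function(n_variables, n_intervals) {
  if (n_intervals < 2 || n_intervals > n_variables)
    stop("need 2 <= n_intervals <= n_variables")
  base <- n_variables %/% n_intervals
  r <- n_variables %% n_intervals
  len <- rep(base, n_intervals)
  if (r > 0) len[seq_len(r)] <- base + 1
  end <- cumsum(len)
  structure(
    data.frame(interval = seq_len(n_intervals),
               start = end - len + 1, end = end, length = len),
    class = c("interval_partition", "data.frame"),
    n_variables = n_variables)
}

#' All interval combinations of the given sizes
#'
#' @param n_intervals number of intervals available.
#' @param sizes combination sizes to enumerate (default `c(2, 3)`).
#' @return List of integer vectors (1-based interval indices), size-2
#'   combinations first, lexicographic within each size. For 25 intervals
#'   and sizes 2 and 3 this is choose(25,2) + choose(25,3) = 2600
#'   combinations.
#' @export
enumerate_combos <- function(n_intervals, sizes = c(2, 3)) {
  if (!length(sizes)) stop("sizes must be nonempty")
  if (any(sizes < 1 | sizes > n_intervals))
    stop("each size must be between 1 and n_intervals")
  out <- list()
  for (s in sort(unique(sizes)))
    out <- c(out, combn(n_intervals, s, simplify = FALSE))
  out
}

interval_columns <- function(part, combo) {
  unlist(lapply(combo, function(i) seq(part$start[i], part$end[i])))
}

# wavelength range(s) spanned by a combo, merging adjacent intervals
combo_regions <- function(part, combo, grid) {
  combo <- sort(combo)
  runs <- split(combo, cumsum(c(1, diff(combo) != 1)))
  do.call(rbind, lapply(runs, function(r) {
    data.frame(from = grid$values[part$start[r[1]]],
               to = grid$values[part$end[r[length(r)]]])
  }))
}

#' Synergy-interval PLS wavelength selection
#'
#' The quantitative core of the pipeline. The spectral axis is divided
#' into `n_intervals` equidistant intervals; for every combination of
#' `sizes` intervals (by default all pairs and triples) the member
#' intervals' variables are concatenated and a PLS calibration is scored
#' by leave-one-out RMSECV at 1..`max_lv` latent variables. The
#' combination/depth pair with the lowest RMSECV wins; ties are broken
#' toward fewer latent variables, then toward the lexicographically
#' smallest combination, so the search is deterministic. Any
#' pretreatment must be applied to the full spectrum beforehand
#' (derivative windows must not straddle interval edges).
#'
#' @param X calibration spectra matrix (pretreated).
#' @param y calibration response (one freshness index).
#' @param grid [make_grid()] axis matching `ncol(X)`.
#' @param n_intervals number of equidistant intervals (default 25).
#' @param sizes combination sizes (default `c(2, 3)`).
#' @param max_lv deepest latent-variable count scored (default 15; capped
#'   per combination by fold rank).
#' @return An object of class `sipls`: `best_combo`, `best_lv`,
#'   `best_rmsecv`, `selected_regions` (nm ranges), the full search
#'   `table` (one row per combination with its optimal depth), the
#'   `partition`, the winning fitted [pls_fit()] model and the RMSECV
#'   curve of the winning combination.
#' @export
sipls <- function(X, y, grid, n_intervals = 25, sizes = c(2, 3),
                  max_lv = 15) {
  X <- as.matrix(X)
  validate_grid(grid)
  if (ncol(X) != length(grid$values)) stop("grid/X variable count mismatch")
  if (n_intervals < max(sizes)) stop("n_intervals must be >= max(sizes)")
  if (sd(y) == 0) stop("zero-variance response: every combination degenerate")
  part <- partition_intervals(ncol(X), n_intervals)
  combos <- enumerate_combos(n_intervals, sizes)
  cols0 <- lapply(combos, function(cb) interval_columns(part, cb) - 1L)
  max_lv <- min(max_lv, nrow(X) - 2)
  cv <- cpp_combo_rmsecv(X, y, cols0, as.integer(max_lv))
  # per-combination optimum, ties toward fewer latent variables
  best_lv_per <- apply(cv, 1, which.min)
  best_cv_per <- cv[cbind(seq_len(nrow(cv)), best_lv_per)]
  tab <- data.frame(
    combo = vapply(combos, paste, "", collapse = "+"),
    n_lv = best_lv_per, rmsecv = best_cv_per, stringsAsFactors = FALSE)
  # global optimum; enumeration order is lexicographic so ties fall to the
  # smallest combination
  ibest <- which.min(best_cv_per)
  combo <- combos[[ibest]]
  lv <- best_lv_per[ibest]
  cols <- interval_columns(part, combo)
  fit <- pls_fit(X[, cols, drop = FALSE], y, lv)
  structure(
    list(best_combo = combo, best_lv = lv,
         best_rmsecv = best_cv_per[ibest],
         selected_regions = combo_regions(part, combo, grid),
         selected_columns = cols,
         table = tab, rmsecv_curve = cv[ibest, ],
         partition = part, grid = grid, model = fit),
    class = "sipls")
}

#' @export
print.sipls <- function(x, ...) {
  cat(sprintf("<sipls> best combination {%s}, %d latent variables, RMSECV %.4g\n",
              paste(x$best_combo, collapse = ", "), x$best_lv, x$best_rmsecv))
  cat("  selected regions:", format_regions(x$selected_regions, x$grid$unit), "\n")
  invisible(x)
}

#' @export
summary.sipls <- function(object, n = 10, ...) {
  tab <- object$table[order(object$table$rmsecv), ]
  cat("Synergy-interval PLS search:", nrow(object$table),
      "interval combinations\n")
  cat("Selected regions:",
      format_regions(object$selected_regions, object$grid$unit), "\n\n")
  print(head(tab, n), row.names = FALSE)
  invisible(tab)
}

#' Predict from the winning Si-PLS model
#' @param object a [sipls()] result.
#' @param newdata full-spectrum matrix on the search grid (the selected
#'   columns are extracted internally).
#' @param ... unused.
#' @return Predicted response vector.
#' @export
predict.sipls <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != length(object$grid$values))
    stop("newdata must be on the full search grid")
  predict(object$model, newdata[, object$selected_columns, drop = FALSE])
}

format_regions <- function(regions, unit = "nm") {
  paste(sprintf("%.0f-%.0f %s", regions$from, regions$to, unit),
        collapse = ", ")
}

#' Evaluate a Si-PLS calibration on an independent prediction set
#'
#' Refits PLS on the calibration set restricted to the winning intervals at
#' the winning depth, then reports the root-mean-square error of
#' prediction (RMSEP) and the reference-vs-predicted Pearson correlation
#' R(t) on the prediction set.
#'
#' @param result a [sipls()] result (searched on `X_cal`, `y_cal`).
#' @param X_cal,y_cal calibration data (pretreated, full grid).
#' @param X_pred,y_pred prediction data, disjoint from calibration.
#' @return List of class `sipls_eval`: `rmsep`, `r_prediction`,
#'   `rmsecv_curve`, `chosen_lv`, `selected_regions`, `predicted`.
#' @export
evaluate_sipls <- function(result, X_cal, y_cal, X_pred, y_pred) {
  stopifnot(inherits(result, "sipls"))
  cols <- result$selected_columns
  fit <- pls_fit(as.matrix(X_cal)[, cols, drop = FALSE], y_cal,
                 result$best_lv)
  yhat <- predict(fit, as.matrix(X_pred)[, cols, drop = FALSE])
  structure(
    list(rmsep = rmsep(y_pred, yhat),
         r_prediction = pearson_r(y_pred, yhat),
         rmsecv_curve = result$rmsecv_curve,
         chosen_lv = result$best_lv,
         selected_regions = result$selected_regions,
         predicted = yhat),
    class = "sipls_eval")
}

#' @export
print.sipls_eval <- function(x, ...) {
  cat(sprintf("<sipls_eval> RMSEP %.4g, R(t) %.3f, %d latent variables\n",
              x$rmsep, x$r_prediction, x$chosen_lv))
  cat("  regions:", format_regions(x$selected_regions), "\n")
  invisible(x)
}
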