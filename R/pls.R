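#' Partial least squares regression (NIPALS, single response)
#'
#' Fits a PLS1 calibration of a scalar response (a freshness index) on a
#' spectra matrix by NIPALS. X and y are mean-centered; variance scaling is
#' not applied by default (derivative or SNV pretreatment already
#' equalizes scales) but can be switched on. With one response the NIPALS
#' weight vector is exact in a single pass per latent variable, so no inner
#' iteration is needed; extraction stops early if the deflated X loses
#' rank. The sequential model is collapsed into a regression vector, and
#' the coefficient path for every intermediate latent-variable count is
#' retained so cross-validation can score all model sizes from one fit.
#'
#' @param X numeric matrix, rows = samples.
#' @param y numeric response vector with positive variance.
#' @param n_lv number of latent variables,
#'   `<= min(n_samples - 1, n_variables)`.
#' @param scale logical; autoscale columns of X to unit variance before
#'   fitting (default `FALSE`, centering only).
#' @return An object of class `pls1`: means, `weights`, `x_loadings`,
#'   `y_loadings`, `regression_vector` (for the full model), `coef_path`
#'   (coefficients for 1..n_lv latent variables), training `scores` and
#'   `fitted`.
#' @export
pls_fit <- function(X, y, n_lv, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length of y must match rows of X")
  if (sd(y) == 0) stop("zero-variance response")
  if (n_lv < 1 || n_lv > min(n - 1, ncol(X)))
    stop("n_lv must be between 1 and min(n_samples - 1, n_variables)")
  x_scale <- rep(1, ncol(X))
  if (scale) {
    x_scale <- apply(X, 2, sd)
    x_scale[x_scale == 0] <- 1
    X <- sweep(X, 2, x_scale, `/`)
  }
  f <- cpp_pls1(X, y, as.integer(n_lv))
  if (f$n_lv < n_lv)
    warning("rank loss: only ", f$n_lv, " of ", n_lv,
            " latent variables extracted")
  b <- f$coef_path[, f$n_lv]
  fitted <- f$y_mean + (sweep(X, 2, drop(f$x_mean)) %*% b)[, 1]
  structure(
    list(n_lv = f$n_lv, x_mean = drop(f$x_mean), y_mean = f$y_mean,
         x_scale = x_scale, scaled = scale,
         weights = f$weights, x_loadings = f$x_loadings,
         y_loadings = drop(f$y_loadings),
         regression_vector = b, coef_path = f$coef_path,
         scores = f$scores, fitted = fitted, residuals = y - fitted),
    class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1> %d latent variables, %d spectral variables\n",
              x$n_lv, length(x$x_mean)))
  cat(sprintf("  training RMSE %.4g\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.pls1 <- function(object, n_lv = object$n_lv, ...) {
  object$coef_path[, n_lv]
}

#' Predict a freshness index from spectra with a PLS calibration
#' @param object a [pls_fit()] model.
#' @param newdata matrix (or single spectrum) with the training variable
#'   count.
#' @param n_lv latent-variable count to predict with (any value up to the
#'   fitted depth; defaults to the full model).
#' @param ... unused.
#' @return Numeric vector `y_mean + (X - x_mean) %*% b`.
#' @export
predict.pls1 <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("variable count mismatch")
  if (object$scaled) newdata <- sweep(newdata, 2, object$x_scale, `/`)
  b <- object$coef_path[, n_lv]
  drop(object$y_mean + sweep(newdata, 2, object$x_mean) %*% b)
}

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' Leave-one-out cross-validated RMSE per latent-variable count
#'
#' Full (leave-one-out) cross-validation: each sample is held out in turn,
#' the model is refit on the remaining samples with fold-level
#' re-centering (no information from the held-out sample enters the fold),
#' and the held-out prediction error is accumulated. The returned curve
#' `RMSECV(k) = sqrt(mean((y - yhat_loo_k)^2))` is the model-size selection
#' criterion used throughout the interval search; its minimizer, with ties
#' broken toward fewer latent variables, is the chosen model depth.
#'
#' @param X,y calibration data; at least 3 samples.
#' @param max_lv deepest model to score, `<= n_samples - 2` (each fold
#'   drops one sample).
#' @param scale autoscale within each fold (default `FALSE`).
#' @return Numeric vector of RMSECV values for 1..max_lv latent variables.
#' @export
loo_rmsecv <- function(X, y, max_lv, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for leave-one-out")
  if (max_lv < 1 || max_lv > min(n - 2, ncol(X)))
    stop("max_lv must be between 1 and min(n_samples - 2, n_variables)")
  if (sd(y) == 0) return(rep(0, max_lv))
  if (scale) stop("autoscaled cross-validation is not implemented")
  pred <- cpp_loo_pred(X, y, as.integer(max_lv))
  sqrt(colMeans((pred - y)^2))
}

#' Root-mean-square error of prediction
#' @param y_true,y_pred equal-length numeric vectors (length >= 2).
#' @return `sqrt(mean((y_true - y_pred)^2))`, in response units.
#' @export
rmsep <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2)
    stop("need equal-length vectors of length >= 2")
  sqrt(mean((y_true - y_pred)^2))
}

#' Pearson correlation between reference and predicted values
#' @param y_true,y_pred equal-length non-constant numeric vectors.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2)
    stop("need equal-length vectors of length >= 2")
  if (sd(y_true) == 0 || sd(y_pred) == 0)
    stop("correlation undefined for a constant vector")
  cor(y_true, y_pred)
}
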