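#' Principal component analysis of spectra
#'
#' Column-mean-centered PCA computed by singular value decomposition of the
#' centered matrix (numerically preferable to forming the covariance).
#' Component signs are fixed by making each loading's largest-magnitude
#' element positive, so score plots are reproducible across platforms.
#'
#' @param X numeric matrix, rows = samples; at least 2 rows.
#' @param k number of components to retain,
#'   `k <= min(n_samples - 1, n_variables)`.
#' @return An object of class `spectra_pca`: `mean_spectrum`, `loadings`
#'   (`n_variables x k`, orthonormal columns), `explained_ratio` (fraction
#'   of total centered variance per component, non-increasing) and
#'   `scores` of the training data.
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  kmax <- min(n - 1, ncol(X))
  if (k < 1 || k > kmax)
    stop("k must be between 1 and min(n_samples - 1, n_variables) = ", kmax)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2)
  if (total_var == 0) stop("constant matrix: total variance is zero")
  sv <- svd(Xc, nu = 0, nv = kmax)
  flip <- vapply(seq_len(kmax), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  V <- sweep(sv$v, 2, flip, `*`)
  structure(
    list(mean_spectrum = mu,
         loadings = V[, seq_len(k), drop = FALSE],
         explained_ratio = (sv$d^2 / total_var)[seq_len(k)],
         scores = Xc %*% V[, seq_len(k), drop = FALSE]),
    class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("<spectra_pca> %d components, cumulative variance %.1f%%\n",
              k, 100 * sum(x$explained_ratio)))
  cat("  explained (%):",
      paste(sprintf("%.2f", 100 * x$explained_ratio), collapse = ", "), "\n")
  invisible(x)
}

#' Project new spectra onto fitted principal components
#' @param object a [pca_fit()] model.
#' @param newdata matrix with the training variable count.
#' @param ... unused.
#' @return Score matrix `(X - mean) %*% loadings`.
#' @export
predict.spectra_pca <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != length(object$mean_spectrum))
    stop("variable count mismatch: model has ",
         length(object$mean_spectrum), ", data has ", ncol(newdata))
  sweep(newdata, 2, object$mean_spectrum) %*% object$loadings
}

#' Cumulative explained variance of leading components
#' @param explained_pct per-component explained variance, in percent.
#' @param k how many leading components to accumulate.
#' @return Their sum (percent).
#' @export
cumulative_explained <- function(explained_pct, k = length(explained_pct)) {
  sum(explained_pct[seq_len(k)])
}
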