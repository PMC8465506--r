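#' Spectral pretreatment configuration
#'
#' Holds the pretreatment choice and the Savitzky-Golay smoothing
#' parameters used by the derivative filters. Defaults follow common
#' chemometrics practice: a 15-point window with a quadratic local
#' polynomial, and the first derivative as the pipeline default
#' pretreatment (it removes per-sample additive baseline offsets while
#' preserving band positions).
#'
#' @param method one of `"none"`, `"snv"`, `"msc"`, `"deriv1"`, `"deriv2"`.
#' @param sg_window odd integer, filter window length in points; must be at
#'   least `sg_polyorder + 2`.
#' @param sg_polyorder local polynomial order; must be at least the
#'   derivative order.
#' @param msc_reference `"calibration_mean"` (reference computed from the
#'   calibration rows only) or `"supplied"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(method = c("deriv1", "none", "snv", "msc", "deriv2"),
                              sg_window = 15, sg_polyorder = 2,
                              msc_reference = c("calibration_mean", "supplied")) {
  method <- match.arg(method)
  msc_reference <- match.arg(msc_reference)
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_window < sg_polyorder + 2)
    stop("sg_window must be at least sg_polyorder + 2")
  ord <- switch(method, deriv1 = 1L, deriv2 = 2L, 0L)
  if (ord > sg_polyorder)
    stop("derivative order exceeds sg_polyorder")
  structure(list(method = method, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 msc_reference = msc_reference),
            class = "preprocess_config")
}

#' Standard normal variate transform of one spectrum
#'
#' Centers the spectrum to mean zero and scales it to unit sample standard
#' deviation (n - 1 denominator). Removes per-sample additive offsets and
#' multiplicative scatter: `snv(a * x + b) == snv(x)` for any `a > 0`.
#'
#' @param x numeric spectrum vector of length >= 2 with positive variance.
#' @param sample_id optional label used in the zero-variance error message.
#' @return The standardized spectrum.
#' @export
snv <- function(x, sample_id = NULL) {
  if (length(x) < 2) stop("snv needs at least 2 points")
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance (constant) spectrum",
         if (!is.null(sample_id)) paste0(" for sample ", sample_id) else "")
  (x - mean(x)) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, `x = a * reference + b`, and returns the corrected row
#' `(x - b) / a`. Rows that are affine transforms of the reference are
#' mapped back onto it exactly.
#'
#' @param X spectra matrix (rows = samples) or a single spectrum vector.
#' @param reference reference spectrum, typically the calibration-set mean;
#'   must have nonzero variance.
#' @return Corrected matrix with the dimensions of `X`.
#' @export
msc <- function(X, reference) {
  one_row <- is.null(dim(X))
  X <- rbind(X)
  if (ncol(X) != length(reference)) stop("reference length mismatch")
  vr <- sum((reference - mean(reference))^2)
  if (vr == 0) stop("zero-variance (constant) MSC reference")
  rc <- reference - mean(reference)
  out <- X
  for (i in seq_len(nrow(X))) {
    a <- sum((X[i, ] - mean(X[i, ])) * rc) / vr
    if (abs(a) < 1e-12)
      stop("degenerate MSC slope (|a| < 1e-12) for row ", i)
    b <- mean(X[i, ]) - a * mean(reference)
    out[i, ] <- (X[i, ] - b) / a
  }
  if (one_row) drop(out) else out
}

#' Savitzky-Golay derivative of spectra
#'
#' Convolution derivative on a uniform grid, scaled by the grid step so the
#' output is in absorbance per axis unit (e.g. per nm). Edges are handled
#' by fitting the local polynomial at the ends rather than truncating, so
#' the output has the same length as the input and downstream interval
#' bookkeeping is unaffected. Exact for polynomials up to the configured
#' polynomial order.
#'
#' @param X spectra matrix (rows = samples) or a single spectrum vector.
#' @param order derivative order (1 or 2).
#' @param step grid step in axis units.
#' @param window,polyorder Savitzky-Golay parameters, see
#'   [preprocess_config()].
#' @return Derivative matrix with the dimensions of `X`.
#' @export
sg_derivative <- function(X, order, step, window = 15, polyorder = 2) {
  one_row <- is.null(dim(X))
  X <- rbind(X)
  if (window %% 2 != 1) stop("window must be odd")
  if (order > polyorder) stop("derivative order exceeds polyorder")
  if (ncol(X) < window) stop("window larger than spectrum")
  if (!is.finite(step) || step <= 0)
    stop("uniform grid with positive step required")
  filt <- signal::sgolay(p = polyorder, n = window, m = order, ts = step)
  out <- t(apply(X, 1, function(r) signal::sgolayfilt(r, filt)))
  if (one_row) drop(out) else out
}

#' Apply a pretreatment to a spectra collection without leakage
#'
#' SNV and derivatives act row-wise and are leakage-free by construction.
#' MSC needs a reference spectrum: with `msc_reference =
#' "calibration_mean"` it is computed from the calibration rows only and
#' reused for every other row, so no information flows from the prediction
#' set into the treatment.
#'
#' @param s a [spectra_set()].
#' @param cfg a [preprocess_config()].
#' @param calibration_indices row indices defining the MSC reference;
#'   required (nonempty) for `method = "msc"` with the calibration-mean
#'   reference.
#' @param reference supplied reference spectrum when `msc_reference =
#'   "supplied"`.
#' @return A `spectra_set` with the treated absorbance matrix.
#' @export
apply_preprocess <- function(s, cfg, calibration_indices = NULL,
                             reference = NULL) {
  stopifnot(inherits(s, "spectra_set"), inherits(cfg, "preprocess_config"))
  X <- s$absorbance
  Y <- switch(cfg$method,
    none = X,
    snv = t(apply(X, 1, snv)),
    msc = {
      ref <- if (cfg$msc_reference == "supplied") {
        if (is.null(reference)) stop("supplied MSC reference missing")
        reference
      } else {
        if (is.null(calibration_indices) || !length(calibration_indices))
          stop("calibration_indices required for MSC with calibration_mean reference")
        colMeans(X[calibration_indices, , drop = FALSE])
      }
      msc(X, ref)
    },
    deriv1 = sg_derivative(X, 1, s$grid$step, cfg$sg_window, cfg$sg_polyorder),
    deriv2 = sg_derivative(X, 2, s$grid$step, cfg$sg_window, cfg$sg_polyorder))
  dimnames(Y) <- dimnames(X)
  out <- s
  out$absorbance <- Y
  out
}
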