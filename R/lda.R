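#' Linear discriminant analysis on score vectors
#'
#' Gaussian classifier with class-specific means and a shared (pooled
#' within-class) covariance — the storage-day discriminator applied to
#' principal-component scores. Priors are equal by default, matching the
#' balanced design of the emulated study (10 calibration eggs per day);
#' empirical priors can be supplied. A ridge `regularization * I` is added
#' to the pooled covariance: 13 score dimensions estimated from 70 samples
#' across 7 classes leave few degrees of freedom, so the default
#' regularization `1e-6 * trace / n_scores` guards against
#' near-singularity without noticeably moving the boundaries.
#'
#' @param scores numeric matrix, rows = samples (typically PCA scores).
#' @param labels class label per sample (storage day); at least 2 classes
#'   with at least 2 samples each.
#' @param regularization ridge added to the pooled covariance, as a
#'   fraction of `trace / n_scores`; `NULL` for the default `1e-6` scaling,
#'   `0` for none.
#' @param priors `"equal"` (default) or `"empirical"`.
#' @return Object of class `pc_lda`: `classes` (sorted), `class_means`,
#'   `pooled_covariance` (after regularization), `priors`,
#'   `regularization`.
#' @export
lda_fit <- function(scores, labels, regularization = NULL,
                    priors = c("equal", "empirical")) {
  scores <- as.matrix(scores)
  priors <- match.arg(priors)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  n <- nrow(scores)
  p <- ncol(scores)
  mus <- do.call(rbind, lapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  centered <- scores - mus[match(labels, classes), , drop = FALSE]
  S <- crossprod(centered) / (n - length(classes))
  lam <- if (is.null(regularization)) 1e-6 * sum(diag(S)) / p
         else regularization
  if (lam < 0) stop("regularization must be >= 0")
  S <- S + diag(lam, p)
  ev <- tryCatch(chol(S), error = function(e)
    stop("singular pooled covariance; increase regularization"))
  pr <- if (priors == "equal") rep(1 / length(classes), length(classes))
        else as.numeric(counts) / n
  structure(
    list(classes = classes, class_means = mus, pooled_covariance = S,
         priors = pr, regularization = lam, chol = ev),
    class = "pc_lda")
}

#' @export
print.pc_lda <- function(x, ...) {
  cat(sprintf("<pc_lda> %d classes (%s), %d score dimensions\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$class_means)))
  invisible(x)
}

#' Classify score vectors with a fitted discriminant
#'
#' Assigns each row to the class maximizing the linear Gaussian
#' discriminant `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log(prior_k)` with
#' the shared covariance `S`. Exact ties go to the earlier class label.
#'
#' @param object a [lda_fit()] model.
#' @param newdata score matrix with the training dimensionality.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.pc_lda <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != ncol(object$class_means))
    stop("score dimensionality mismatch")
  Sinv_mu <- backsolve(object$chol,
                       forwardsolve(t(object$chol), t(object$class_means)))
  d <- newdata %*% Sinv_mu
  d <- sweep(d, 2, colSums(t(object$class_means) * Sinv_mu) / 2)
  d <- sweep(d, 2, log(object$priors), `+`)
  object$classes[apply(d, 1, which.max)]
}

#' Qualitative storage-day discrimination pipeline
#'
#' End-to-end discriminant analysis of a spectra collection: pretreat the
#' spectra (leakage-free), fit PCA on the calibration rows only, project
#' both sets onto the leading components, fit the discriminant on
#' calibration scores, and count per-day correct classifications in both
#' sets. The default of 13 principal components follows the depth at
#' which the room-temperature discrimination of the emulated study was
#' optimal.
#'
#' The default pretreatment for this qualitative stage is SNV: it
#' removes the per-sample gain and offset artifacts exactly without
#' amplifying channel noise, whereas a derivative filter inflates the
#' noisy detector-edge channels into spurious high-variance score
#' directions. (The quantitative calibration keeps the first derivative
#' as its default; see [preprocess_config()].)
#'
#' @param s a [spectra_set()].
#' @param cfg a [preprocess_config()].
#' @param n_pcs principal components used as discriminant inputs
#'   (default 13).
#' @param split a [make_split()] plan (defaults to the every-third rule).
#' @param regularization passed to [lda_fit()].
#' @return List of class `qualify_report`: `per_day` data.frame (day,
#'   train correct/total, test correct/total), `train_accuracy` and
#'   `test_accuracy` (one-decimal percentages), `confusion` (test-set
#'   class x class counts), `n_pcs`.
#' @export
qualify_pipeline <- function(s, cfg = preprocess_config("snv"), n_pcs = 13,
                             split = make_split(s), regularization = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  cal <- split$calibration
  prd <- split$prediction
  sp <- apply_preprocess(s, cfg, calibration_indices = cal)
  pca <- pca_fit(sp$absorbance[cal, , drop = FALSE], n_pcs)
  sc_cal <- predict(pca, sp$absorbance[cal, , drop = FALSE])
  sc_prd <- predict(pca, sp$absorbance[prd, , drop = FALSE])
  day_cal <- s$metadata$storage_day[cal]
  day_prd <- s$metadata$storage_day[prd]
  model <- lda_fit(sc_cal, day_cal, regularization = regularization)
  hat_cal <- as.integer(predict(model, sc_cal))
  hat_prd <- as.integer(predict(model, sc_prd))
  days <- sort(unique(s$metadata$storage_day))
  per_day <- data.frame(
    storage_day = days,
    train_correct = vapply(days, function(d)
      sum(hat_cal == d & day_cal == d), 0L),
    train_total = vapply(days, function(d) sum(day_cal == d), 0L),
    test_correct = vapply(days, function(d)
      sum(hat_prd == d & day_prd == d), 0L),
    test_total = vapply(days, function(d) sum(day_prd == d), 0L))
  confusion <- table(factor(day_prd, levels = days),
                     factor(hat_prd, levels = days),
                     dnn = c("reference", "predicted"))
  structure(
    list(per_day = per_day,
         train_accuracy = accuracy_from_counts(per_day$train_correct,
                                               per_day$train_total),
         test_accuracy = accuracy_from_counts(per_day$test_correct,
                                              per_day$test_total),
         confusion = confusion, n_pcs = n_pcs, model = model),
    class = "qualify_report")
}

#' @export
print.qualify_report <- function(x, ...) {
  cat(sprintf("<qualify_report> %d PCs\n", x$n_pcs))
  tab <- x$per_day
  cat(sprintf("  day %2d: train %d/%d, test %d/%d\n", tab$storage_day,
              tab$train_correct, tab$train_total,
              tab$test_correct, tab$test_total), sep = "")
  cat(sprintf("  Total (%%): train %.1f, test %.1f\n",
              x$train_accuracy, x$test_accuracy))
  invisible(x)
}
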