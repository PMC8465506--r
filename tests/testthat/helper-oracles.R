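# Independent oracles, deliberately written in plain R with no shared code
# path with the package internals.

# Naive NIPALS PLS1: returns predictions for newdata at n_lv latent
# variables, via explicit sequential deflation.
oracle_pls1_predict <- function(X, y, newdata, n_lv) {
  X <- as.matrix(X)
  newdata <- as.matrix(newdata)
  xm <- colMeans(X)
  ym <- mean(y)
  E <- sweep(X, 2, xm)
  f <- y - ym
  W <- P <- matrix(0, ncol(X), n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    q[a] <- sum(f * t) / sum(t^2)
    E <- E - tcrossprod(t, p)
    f <- f - q[a] * t
    W[, a] <- w
    P[, a] <- p
  }
  pred <- rep(ym, nrow(newdata))
  Xc <- sweep(newdata, 2, xm)
  for (a in seq_len(n_lv)) {
    t_new <- drop(Xc %*% W[, a])
    Xc <- Xc - tcrossprod(t_new, P[, a])
    pred <- pred + q[a] * t_new
  }
  pred
}

# Brute-force leave-one-out RMSECV: refit from scratch per fold.
oracle_loo_rmsecv <- function(X, y, max_lv) {
  n <- nrow(X)
  errs <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    for (k in seq_len(max_lv)) {
      p <- oracle_pls1_predict(X[-i, , drop = FALSE], y[-i],
                               X[i, , drop = FALSE], k)
      errs[i, k] <- p - y[i]
    }
  }
  sqrt(colMeans(errs^2))
}

# Minimal valid spectra_set on a uniform grid.
toy_spectra <- function(n = 6, p = 30, seed = 42,
                        days = rep(c(1, 3, 5), length.out = n)) {
  set.seed(seed)
  g <- make_grid(600, 600 + p, 1)
  stopifnot(length(g$values) == p)
  spectra_set(matrix(rnorm(n * p, mean = 1), n, p), g,
              sprintf("egg%02d", seq_len(n)),
              data.frame(storage_day = days, temp_group = "25C",
                         replicate = seq_len(n)))
}

# The thinned grid used by the simulation-based checks (about 400
# variables over the instrument range).
thin_grid <- function() make_grid(550, 985, 1.09)
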