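# Independent reference implementations used as test oracles.  These are
# deliberately written along different algebraic routes than the package
# (Krylov-subspace least squares instead of NIPALS deflation; per-window
# polynomial fits instead of convolution filters) so agreement is evidence,
# not tautology.

# PLS1 via the Krylov-subspace characterization: the k-component PLS1
# solution is the least-squares fit of y on X restricted to
# span{X'y, (X'X)X'y, ..., (X'X)^(k-1) X'y}.
oracle_pls1 <- function(X, y, k) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-"); yc <- y - ym
  K <- matrix(0, ncol(Xc), k)
  v <- crossprod(Xc, yc)
  for (j in seq_len(k)) {
    v <- v / sqrt(sum(v^2))
    K[, j] <- v
    v <- crossprod(Xc, Xc %*% v)
  }
  Q <- qr.Q(qr(K))
  Z <- Xc %*% Q
  gamma <- qr.coef(qr(Z), yc)
  b <- as.numeric(Q %*% gamma)
  list(
    coef = b,
    predict = function(Xn) {
      as.numeric(sweep(as.matrix(Xn), 2, xm, "-") %*% b + ym)
    }
  )
}

# Savitzky-Golay derivative by an explicit windowed polynomial least-squares
# fit at each interior point: the d-th derivative at the window center is
# d! times the t^d coefficient of the local fit (t = offset in index steps).
oracle_savgol <- function(x, window, polyorder, deriv) {
  half <- (window - 1L) / 2L
  n <- length(x)
  vapply((half + 1L):(n - half), function(i) {
    t <- (-half):half
    fit <- lm(x[(i - half):(i + half)] ~ poly(t, polyorder, raw = TRUE))
    factorial(deriv) * unname(coef(fit)[deriv + 1L])
  }, numeric(1))
}

# grouped leave-one-sample-out CV refitted from scratch per fold with the
# Krylov oracle
oracle_loocv <- function(X, y, groups, max_lv) {
  gs <- unique(groups)
  press <- numeric(max_lv)
  cnt <- integer(max_lv)
  for (g in gs) {
    h <- groups == g
    kmax <- min(max_lv, sum(!h) - 1L, ncol(X))
    for (k in seq_len(kmax)) {
      fit <- oracle_pls1(X[!h, , drop = FALSE], y[!h], k)
      press[k] <- press[k] + sum((fit$predict(X[h, , drop = FALSE]) - y[h])^2)
      cnt[k] <- cnt[k] + sum(h)
    }
  }
  out <- sqrt(press / cnt)
  out[cnt < length(y)] <- NA_real_
  out
}

# small, fast simulation configs used across tests
tinyConfig <- function(seed = 1, ...) {
  simulationConfig(seed = seed, n_cultivars = 8L, regions = "RA",
                   seasons = "spring", ...)
}

# scatter-free configuration for exact-recovery checks: no baseline, no
# scatter, no noise (SNV is skipped by the matching chain below)
cleanConfig <- function(seed = 1, n_cultivars = 12L, ...) {
  simulationConfig(seed = seed, n_cultivars = n_cultivars, regions = "RA",
                   seasons = "spring", baseline_intercept_sd = 0,
                   baseline_slope_sd = 0, scatter_sd = 0, noise_sd = 0, ...)
}

cleanChain <- function() preprocessConfig(apply_snv = FALSE)

# one-Gaussian single-analyte configuration (no interferents) for
# closed-form spectral checks
singleBandConfig <- function(seed = 1, amplitude = 1e-3, center = 6000,
                             width = 60, ...) {
  simulationConfig(
    seed = seed, n_cultivars = 6L, regions = "RA", seasons = "spring",
    analyte_bands = list(TPC = data.frame(center = center, width = width,
                                          amplitude = amplitude)),
    interferent_bands = data.frame(center = 5200, width = 120, amplitude = 0),
    baseline_intercept_sd = 0, baseline_slope_sd = 0, scatter_sd = 0,
    noise_sd = 0, ...
  )
}
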