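## NIPALS PLS1 with deflation of X only.  The coefficient path for all
## component counts 1..k is kept so that cross-validation can score every
## model size from a single decomposition per fold.

.nipals <- function(Xc, yc, nLV, tol = 1e-12) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, nLV); P <- matrix(0, p, nLV)
  q <- numeric(nLV); Tm <- matrix(0, n, nLV)
  Xd <- Xc
  k <- 0L
  for (a in seq_len(nLV)) {
    w <- crossprod(Xd, yc)                    # p x 1
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < tol) break     # rank exhausted
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < tol) break
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yc * t) / tt
    Xd <- Xd - t %*% t(pvec)
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa; Tm[, a] <- t
    k <- a
  }
  if (k == 0L) stop("X carries no covariance with y; cannot extract a component")
  list(W = W[, seq_len(k), drop = FALSE],
       P = P[, seq_len(k), drop = FALSE],
       q = q[seq_len(k)],
       scores = Tm[, seq_len(k), drop = FALSE],
       nLV = k)
}

# regression vectors for every component count 1..nLV (p x nLV matrix)
.coefPath <- function(fit) {
  p <- nrow(fit$W)
  B <- matrix(0, p, fit$nLV)
  R <- matrix(0, p, fit$nLV)     # R = W (P'W)^{-1}, built column by column
  for (a in seq_len(fit$nLV)) {
    r <- fit$W[, a]
    if (a > 1) {
      r <- r - R[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(fit$P[, seq_len(a - 1), drop = FALSE], fit$W[, a])
    }
    R[, a] <- r
    B[, a] <- if (a == 1) r * fit$q[1] else B[, a - 1] + r * fit$q[a]
  }
  B
}

#' Fit a PLS1 calibration by NIPALS
#'
#' Deterministic NIPALS PLS1 with deflation of X only.  Centering (columns
#' of X by their calibration means, y by its mean) is performed internally,
#' so the model predicts directly from preprocessed, uncentered spectra.
#' If `nLV` exceeds the effective rank the model is truncated with a
#' warning.
#'
#' @param X numeric matrix, one preprocessed spectrum per row.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param nLV number of latent variables (`>= 1`,
#'   `<= min(nrow(X) - 1, ncol(X))`).
#' @param wavenumbers optional grid labels for the columns of `X`.
#' @param region optional list of `c(low, high)` intervals describing the
#'   spectral region of `X`'s columns.
#' @param regionLabel printable region label.
#' @param preprocess the [preprocessConfig()] applied upstream (metadata).
#' @return a [PLSModel-class].
#' @export
fitPLS <- function(X, y, nLV, wavenumbers = NULL, region = list(),
                   regionLabel = "full spectrum",
                   preprocess = preprocessConfig()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (nrow(X) < 2) stop("need at least 2 calibration rows")
  nLV <- as.integer(nLV)
  if (nLV < 1) stop("nLV must be >= 1")
  maxLV <- min(nrow(X) - 1L, ncol(X))
  if (nLV > maxLV) {
    warning("nLV truncated from ", nLV, " to ", maxLV)
    nLV <- maxLV
  }
  xm <- colMeans(X); ym <- mean(y)
  fit <- .nipals(sweep(X, 2, xm, "-"), y - ym, nLV)
  if (fit$nLV < nLV) {
    warning("rank exhausted: only ", fit$nLV, " components extracted")
  }
  b <- as.numeric(.coefPath(fit)[, fit$nLV])
  if (is.null(wavenumbers)) wavenumbers <- as.numeric(seq_len(ncol(X)))
  new("PLSModel",
      nLV = fit$nLV, xMean = xm, yMean = ym,
      weights = fit$W, xLoadings = fit$P, yLoadings = fit$q,
      coefficients = b, wavenumbers = as.numeric(wavenumbers),
      region = region, regionLabel = regionLabel,
      preprocess = unclass(preprocess))
}

#' Predict from a fitted PLSModel
#'
#' @param object a [PLSModel-class].
#' @param newdata matrix of preprocessed spectra (one per row), restricted
#'   to the model's spectral region; column count must match.
#' @param ... unused.
#' @return numeric vector of predictions
#'   `(newdata - xMean) %*% b + yMean`.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@xMean)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object@xMean))
  }
  as.numeric(sweep(newdata, 2, object@xMean, "-") %*% object@coefficients +
               object@yMean)
})

#' Grouped leave-one-out cross-validation for PLS1
#'
#' Leave-one-SAMPLE-out: all replicate spectra sharing a group label are
#' held out together, the model (including centering) is refitted on the
#' remaining rows and the held-out rows are predicted.  RMSECV is reported
#' for every component count `1..max_lv`.  The spectrum-level variant
#' (`groups = seq_len(nrow(X))`) is available by passing per-row groups.
#'
#' @param X preprocessed spectral matrix (rows = spectra).
#' @param y response vector.
#' @param groups grouping vector (sample ids), one entry per row.
#' @param max_lv maximum component count to score.
#' @return numeric vector `rmsecv` of length `max_lv` (entries for
#'   component counts unreachable in some fold are `NA`, with a warning).
#' @export
loocv <- function(X, y, groups, max_lv = 10L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(groups) == length(y))
  gs <- unique(groups)
  if (length(gs) < 3) stop("grouped LOOCV needs at least 3 groups")
  max_lv <- as.integer(max_lv)
  if (max_lv < 1) stop("max_lv must be >= 1")
  press <- numeric(max_lv)    # sum of squared held-out residuals per k
  count <- integer(max_lv)
  reached <- max_lv
  for (g in gs) {
    hold <- groups == g
    Xtr <- X[!hold, , drop = FALSE]; ytr <- y[!hold]
    kmax <- min(max_lv, nrow(Xtr) - 1L, ncol(Xtr))
    xm <- colMeans(Xtr); ym <- mean(ytr)
    fit <- .nipals(sweep(Xtr, 2, xm, "-"), ytr - ym, kmax)
    B <- .coefPath(fit)
    Xh <- sweep(X[hold, , drop = FALSE], 2, xm, "-")
    pred <- Xh %*% B + ym                       # nheld x fit$nLV
    res2 <- (pred - y[hold])^2
    ks <- seq_len(fit$nLV)
    press[ks] <- press[ks] + colSums(res2)
    count[ks] <- count[ks] + sum(hold)
    reached <- min(reached, fit$nLV)
  }
  if (reached < max_lv) {
    warning("component counts above ", reached,
            " were not reachable in every fold and are reported as NA")
  }
  rmsecv <- sqrt(press / count)
  rmsecv[count < length(y)] <- NA_real_
  rmsecv
}

#' Select the number of latent variables (parsimony rule)
#'
#' Returns the smallest component count whose RMSECV is within
#' `tolerance` (relative) of the curve's minimum; `tolerance = 0` gives the
#' global minimum.
#'
#' @param rmsecv numeric RMSECV curve (index = component count); `NA`
#'   entries are ignored.
#' @param tolerance relative slack, default 0.02 (2\%).
#' @return integer component count.
#' @export
selectLV <- function(rmsecv, tolerance = 0.02) {
  if (!length(rmsecv) || all(is.na(rmsecv))) stop("empty RMSECV curve")
  lo <- min(rmsecv, na.rm = TRUE)
  ok <- which(!is.na(rmsecv) & rmsecv <= (1 + tolerance) * lo)
  as.integer(ok[1])
}
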