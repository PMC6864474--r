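#' Preprocessing configuration
#'
#' The standard pre-treatment chain for diffuse-reflectance leaf spectra:
#' standard normal variate (per spectrum), Savitzky-Golay derivative
#' filtering (default 15-point window, 2nd-order polynomial, 1st
#' derivative), then mean centering at model-fit time (calibration means
#' only).  The step order is fixed as SNV, then Savitzky-Golay, then
#' centering; either of the first two steps can be switched off.
#'
#' @param apply_snv logical, apply SNV.
#' @param savgol_window odd window length (points); 0 or `NA` disables the
#'   filter.
#' @param savgol_polyorder polynomial order.
#' @param savgol_derivative derivative order (0 = smoothing only).
#' @param mean_center logical; recorded here, applied inside [fitPLS()].
#' @param snv_first if `FALSE`, run the Savitzky-Golay step before SNV
#'   (the alternative convention).
#' @return a validated list of class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(apply_snv = TRUE, savgol_window = 15L,
                             savgol_polyorder = 2L, savgol_derivative = 1L,
                             mean_center = TRUE, snv_first = TRUE) {
  cfg <- structure(list(
    apply_snv = isTRUE(apply_snv),
    savgol_window = as.integer(savgol_window),
    savgol_polyorder = as.integer(savgol_polyorder),
    savgol_derivative = as.integer(savgol_derivative),
    mean_center = isTRUE(mean_center),
    snv_first = isTRUE(snv_first)
  ), class = "PreprocessConfig")
  if (!is.na(cfg$savgol_window) && cfg$savgol_window > 0) {
    if (cfg$savgol_window %% 2 == 0) stop("savgol_window must be odd")
    if (cfg$savgol_window <= cfg$savgol_polyorder) {
      stop("savgol_window must exceed savgol_polyorder")
    }
    if (cfg$savgol_derivative > cfg$savgol_polyorder) {
      stop("savgol_derivative must not exceed savgol_polyorder")
    }
  }
  cfg
}

#' Standard normal variate
#'
#' Centers and scales each spectrum to mean 0 and sample (n-1 denominator)
#' standard deviation 1, removing per-spectrum offset and multiplicative
#' scatter.
#'
#' @param x numeric vector (one spectrum) or matrix with one spectrum per
#'   row.
#' @return object of the same shape.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, snv)))
  }
  if (length(x) < 2) stop("SNV needs at least 2 points")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero-variance spectrum: SNV undefined")
  }
  (x - mean(x)) / s
}

#' Savitzky-Golay derivative filter (edges dropped)
#'
#' Each interior point is replaced by the configured derivative of the local
#' least-squares polynomial over the centered window, expressed per index
#' step.  The first and last `(window-1)/2` points are dropped (no
#' extrapolated edges), so the wavenumber grid shrinks by `window - 1`
#' points.  Filter coefficients come from [signal::sgolay()].
#'
#' @param x numeric vector (one spectrum) or matrix with one spectrum per
#'   row.
#' @param window odd window length.
#' @param polyorder polynomial order (`window > polyorder`).
#' @param derivative derivative order (`<= polyorder`; 0 smooths).
#' @return filtered vector/matrix with `window - 1` fewer points/columns.
#' @export
savgolFilter <- function(x, window = 15L, polyorder = 2L, derivative = 1L) {
  window <- as.integer(window)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (derivative > polyorder) stop("derivative must not exceed polyorder")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (window > n) stop("window exceeds spectrum length")
  cc <- signal::sgolay(p = polyorder, n = window, m = derivative)[
    (window + 1L) / 2L, ]
  half <- (window - 1L) / 2L
  applyOne <- function(v) {
    out <- stats::filter(v, rev(cc), sides = 2)
    as.numeric(out[(half + 1L):(length(v) - half)])
  }
  if (is.matrix(x)) {
    t(apply(x, 1, applyOne))
  } else {
    applyOne(x)
  }
}

#' Mean centering with stored calibration means
#'
#' Column means are computed on the calibration rows only and subtracted
#' from whichever rows they are applied to (calibration or prediction).
#'
#' @param train numeric matrix of calibration rows.
#' @param apply_to matrix to center with the calibration means (defaults to
#'   `train` itself).
#' @return the centered `apply_to` matrix, with the means in attribute
#'   `"center"`.
#' @export
meanCenter <- function(train, apply_to = train) {
  train <- as.matrix(train); apply_to <- as.matrix(apply_to)
  if (!nrow(train)) stop("empty calibration matrix")
  if (ncol(train) != ncol(apply_to)) {
    stop("column-count mismatch between calibration and target matrices")
  }
  mu <- colMeans(train)
  out <- sweep(apply_to, 2, mu, "-")
  attr(out, "center") <- mu
  out
}

#' Apply the preprocessing chain to a SpectraSet or matrix
#'
#' Runs SNV (per spectrum) and the Savitzky-Golay derivative filter in the
#' configured order, returning the transformed spectra-by-points matrix and
#' the surviving wavenumber grid.  Mean centering is recorded in the config
#' but deferred to model fitting, where the calibration means are known.
#'
#' @param x a [SpectraSet-class] or a spectra-by-points matrix.
#' @param config a [preprocessConfig()].
#' @param grid wavenumber grid (required when `x` is a bare matrix).
#' @return list with `X` (matrix, one row per spectrum), `wavenumbers`
#'   (surviving grid), `config`.
#' @export
preprocessChain <- function(x, config = preprocessConfig(), grid = NULL) {
  if (is(x, "SpectraSet")) {
    grid <- wavenumbers(x)
    X <- spectraMatrix(x)
  } else {
    X <- as.matrix(x)
    if (is.null(grid)) grid <- seq_len(ncol(X))
    if (length(grid) != ncol(X)) stop("grid length must match spectrum length")
  }
  doSavgol <- !is.na(config$savgol_window) && config$savgol_window > 0
  steps <- if (config$snv_first) c("snv", "sg") else c("sg", "snv")
  for (s in steps) {
    if (s == "snv" && config$apply_snv) {
      X <- snv(X)
    } else if (s == "sg" && doSavgol) {
      X <- savgolFilter(X, config$savgol_window, config$savgol_polyorder,
                        config$savgol_derivative)
      half <- (config$savgol_window - 1L) / 2L
      grid <- grid[(half + 1L):(length(grid) - half)]
    }
  }
  colnames(X) <- NULL
  list(X = X, wavenumbers = grid, config = config)
}
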