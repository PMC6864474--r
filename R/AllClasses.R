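#' SpectraSet: replicate NIR spectra with sample metadata
#'
#' An S4 container for a set of replicate near-infrared spectra acquired on a
#' single shared wavenumber grid, together with per-spectrum sample metadata
#' (cultivar, species, region, season, plant).  `SpectraSet` extends
#' \linkS4class{SummarizedExperiment}: rows are wavenumber points (descending,
#' instrument convention), columns are individual replicate spectra, the
#' `"absorbance"` assay holds the spectral matrix and `colData` the metadata.
#'
#' @section Validity:
#' \itemize{
#'   \item `rowData(x)$wavenumber_cm1` exists, is strictly decreasing, finite,
#'     and has at least 2 points;
#'   \item the `"absorbance"` assay contains only finite values;
#'   \item `colData` carries `sample_id` and `replicate`; replicate indices
#'     are unique within each sample.
#' }
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso [SpectraSet()] for the constructor, [wavenumbers()],
#'   [spectraMatrix()], [sampleData()].
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!("wavenumber_cm1" %in% colnames(rd))) {
    return("rowData must contain a 'wavenumber_cm1' column")
  }
  wn <- rd$wavenumber_cm1
  if (length(wn) < 2L) msg <- c(msg, "a SpectraSet needs at least 2 wavenumber points")
  if (any(!is.finite(wn))) msg <- c(msg, "wavenumbers must be finite")
  if (length(wn) >= 2L && any(diff(wn) >= 0)) {
    msg <- c(msg, "wavenumbers must be strictly decreasing (instrument convention)")
  }
  if (!("absorbance" %in% SummarizedExperiment::assayNames(object))) {
    msg <- c(msg, "assay 'absorbance' is required")
  } else if (any(!is.finite(assay(object, "absorbance")))) {
    msg <- c(msg, "absorbance values must be finite")
  }
  cd <- colData(object)
  needed <- c("sample_id", "replicate")
  miss <- setdiff(needed, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("colData must contain: ", paste(miss, collapse = ", ")))
  } else if (ncol(object) > 0) {
    key <- paste(cd$sample_id, cd$replicate)
    if (anyDuplicated(key)) {
      msg <- c(msg, "replicate indices must be unique within each sample")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("SpectraSet", .validSpectraSet)

#' PLSModel: a fitted PLS1 calibration
#'
#' Stores everything needed to predict a single response from preprocessed
#' (but uncentered) spectra: the calibration column means `xMean` and response
#' mean `yMean`, the NIPALS weights `W`, x-loadings `P` and y-loadings `q`
#' for each extracted latent variable, the regression vector
#' `b = W (P'W)^{-1} q`, the wavenumber grid the model operates on (after
#' preprocessing and region masking), the spectral region, and the
#' preprocessing configuration used.
#'
#' @slot nLV integer, number of latent variables.
#' @slot xMean numeric, calibration column means (length p).
#' @slot yMean numeric scalar, calibration response mean.
#' @slot weights p x nLV matrix of NIPALS weights (unit norm columns).
#' @slot xLoadings p x nLV matrix of x-loadings.
#' @slot yLoadings numeric vector of y-loadings, length nLV.
#' @slot coefficients numeric regression vector, length p.
#' @slot wavenumbers numeric, the grid (cm-1) the model's columns refer to.
#' @slot region list of c(low, high) closed intervals (cm-1) or empty for
#'   full grid; `regionLabel` a printable label.
#' @slot regionLabel character(1).
#' @slot preprocess list, the [preprocessConfig()] used upstream.
#' @export
setClass("PLSModel",
  representation(
    nLV = "integer",
    xMean = "numeric",
    yMean = "numeric",
    weights = "matrix",
    xLoadings = "matrix",
    yLoadings = "numeric",
    coefficients = "numeric",
    wavenumbers = "numeric",
    region = "list",
    regionLabel = "character",
    preprocess = "list"
  )
)

.validPLSModel <- function(object) {
  msg <- character()
  p <- length(object@xMean)
  if (object@nLV < 1L) msg <- c(msg, "nLV must be >= 1")
  if (length(object@coefficients) != p) msg <- c(msg, "coefficients/xMean length mismatch")
  if (!identical(dim(object@weights), c(p, as.integer(object@nLV)))) {
    msg <- c(msg, "weights must be p x nLV")
  }
  if (!identical(dim(object@xLoadings), c(p, as.integer(object@nLV)))) {
    msg <- c(msg, "xLoadings must be p x nLV")
  }
  if (length(object@yLoadings) != object@nLV) msg <- c(msg, "yLoadings length != nLV")
  if (length(object@yMean) != 1L) msg <- c(msg, "yMean must be scalar")
  # b must be reproducible from W, P, q
  if (!length(msg)) {
    b <- tryCatch(
      object@weights %*% solve(crossprod(object@xLoadings, object@weights),
                               object@yLoadings),
      error = function(e) NULL
    )
    if (is.null(b) || max(abs(b - object@coefficients)) >
          1e-6 * max(1, max(abs(object@coefficients)))) {
      msg <- c(msg, "coefficients are not reproducible from W, P, q")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("PLSModel", .validPLSModel)

#' @describeIn PLSModel-class compact display.
#' @param object a `PLSModel`.
#' @export
setMethod("show", "PLSModel", function(object) {
  cat("PLSModel (NIPALS PLS1)\n")
  cat("  latent variables:", object@nLV, "\n")
  cat("  variables (wavenumber points):", length(object@xMean), "\n")
  cat("  spectral region:", object@regionLabel, "\n")
  pp <- object@preprocess
  if (length(pp)) {
    cat(sprintf(
      "  preprocessing: SNV=%s, SavGol(window=%d, poly=%d, deriv=%d)\n",
      isTRUE(pp$apply_snv), pp$savgol_window, pp$savgol_polyorder,
      pp$savgol_derivative
    ))
  }
  invisible(object)
})

setMethod("show", "SpectraSet", function(object) {
  wn <- rowData(object)$wavenumber_cm1
  cat("SpectraSet with", ncol(object), "spectra on", nrow(object),
      "wavenumber points\n")
  if (nrow(object)) {
    cat(sprintf("  grid: %.0f .. %.0f cm-1\n", wn[1], wn[length(wn)]))
  }
  cd <- colData(object)
  if (ncol(object)) {
    cat("  samples:", length(unique(cd$sample_id)), "\n")
    for (f in c("cultivar", "region", "season")) {
      if (f %in% colnames(cd)) {
        cat(sprintf("  %s: %s\n", f,
                    paste(head(unique(as.character(cd[[f]])), 6), collapse = ", ")))
      }
    }
  }
  invisible(object)
})
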