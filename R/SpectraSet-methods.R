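#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, wavenumber points x spectra.
#' @param wavenumbers numeric vector of wavenumbers in cm-1.  If ascending it
#'   is reordered to descending (and the matrix rows with it).
#' @param sampleData a `data.frame` or [S4Vectors::DataFrame] with one row per
#'   spectrum; must contain `sample_id` and `replicate`, and typically
#'   `cultivar`, `species`, `region`, `season`, `plant_id`.
#'
#' @return a validated [SpectraSet-class] object.
#' @examples
#' wn <- seq(10000, 4000, by = -8)
#' x <- matrix(rnorm(length(wn) * 2), ncol = 2)
#' meta <- data.frame(sample_id = "s1", replicate = 1:2)
#' ss <- SpectraSet(x, wn, meta)
#' @export
SpectraSet <- function(absorbance, wavenumbers, sampleData) {
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(wavenumbers)) {
    stop("nrow(absorbance) must equal length(wavenumbers)")
  }
  ord <- order(wavenumbers, decreasing = TRUE)
  wavenumbers <- wavenumbers[ord]
  absorbance <- absorbance[ord, , drop = FALSE]
  sampleData <- DataFrame(sampleData)
  if (is.null(colnames(absorbance)) &&
      all(c("sample_id", "replicate") %in% colnames(sampleData))) {
    colnames(absorbance) <- paste0(sampleData$sample_id, "__r",
                                   sampleData$replicate)
  }
  rownames(sampleData) <- colnames(absorbance)
  se <- SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = DataFrame(wavenumber_cm1 = wavenumbers),
    colData = sampleData
  )
  new("SpectraSet", se)
}

#' @rdname wavenumbers
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Wavenumber grid of a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return numeric vector of wavenumbers (cm-1, descending).
#' @export
setMethod("wavenumbers", "SpectraSet", function(x) {
  rowData(x)$wavenumber_cm1
})

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Spectral matrix in chemometric orientation
#'
#' Returns the absorbance data as a spectra-by-wavenumbers matrix (one row
#' per replicate spectrum), the orientation used by the PLS machinery.
#'
#' @param x a [SpectraSet-class].
#' @return numeric matrix, `ncol(x)` rows and `nrow(x)` columns.
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x) {
  t(assay(x, "absorbance"))
})

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Per-spectrum sample metadata
#'
#' @param x a [SpectraSet-class].
#' @return a `data.frame` with one row per spectrum.
#' @export
setMethod("sampleData", "SpectraSet", function(x) {
  as.data.frame(colData(x))
})

#' Number of distinct samples in a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return integer count of distinct `sample_id` values.
#' @export
nSamples <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  length(unique(colData(x)$sample_id))
}

## ---- CSV I/O ---------------------------------------------------------------

#' Write a SpectraSet to wide CSV plus a metadata sidecar
#'
#' The spectra file has a first column `wavenumber_cm-1` and one column per
#' replicate spectrum named `<sample_id>__r<replicate>`; the sidecar holds the
#' per-spectrum metadata.
#'
#' @param x a [SpectraSet-class].
#' @param path output CSV path for the spectra.
#' @param metaPath output CSV path for the metadata; defaults to `path` with
#'   a `_meta.csv` suffix.
#' @return invisibly, `c(path, metaPath)`.
#' @export
writeSpectraCSV <- function(x, path, metaPath = NULL) {
  stopifnot(is(x, "SpectraSet"))
  if (is.null(metaPath)) metaPath <- sub("\\.csv$", "_meta.csv", path)
  m <- assay(x, "absorbance")
  df <- data.frame(`wavenumber_cm-1` = wavenumbers(x), check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  write.csv(sampleData(x), metaPath, row.names = FALSE)
  invisible(c(path, metaPath))
}

#' Read spectra from CSV (wide) or JCAMP-DX into a SpectraSet
#'
#' @param path spectra file path.
#' @param metaPath metadata CSV path (CSV format only); when `NULL`, column
#'   names of the form `<sample_id>__r<replicate>` are parsed for metadata,
#'   else each column becomes its own sample.
#' @param format `"csv"` (wide matrix, first column the wavenumbers) or
#'   `"jcamp"` (single-block XYDATA, one spectrum).
#' @param gridTolerance maximum absolute wavenumber disagreement (cm-1)
#'   tolerated when checking a supplied grid against the file.
#' @return a validated [SpectraSet-class].
#' @export
readSpectra <- function(path, metaPath = NULL, format = c("csv", "jcamp"),
                        gridTolerance = 1e-6) {
  format <- match.arg(format)
  if (format == "jcamp") {
    sp <- readJCAMP(path)
    meta <- data.frame(sample_id = sp$title, replicate = 1L)
    return(SpectraSet(matrix(sp$y, ncol = 1), sp$x, meta))
  }
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectra CSV needs a wavenumber column and >= 1 spectrum")
  wn <- df[[1]]
  if (any(is.na(suppressWarnings(as.numeric(wn))))) {
    stop("non-numeric wavenumber cell in column 1 of ", path)
  }
  m0 <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(m0), ncol(m0),
              dimnames = list(NULL, colnames(m0)))
  for (j in seq_along(m0)) {
    v <- suppressWarnings(as.numeric(as.character(m0[[j]])))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric/non-finite absorbance at row %d, column '%s'",
                   bad[1], colnames(m0)[j]))
    }
    m[, j] <- v
  }
  if (!is.null(metaPath)) {
    meta <- read.csv(metaPath)
    if (nrow(meta) != ncol(m)) stop("metadata rows != spectra columns")
  } else if (all(grepl("__r[0-9]+$", colnames(m)))) {
    meta <- data.frame(
      sample_id = sub("__r[0-9]+$", "", colnames(m)),
      replicate = as.integer(sub("^.*__r", "", colnames(m)))
    )
  } else {
    meta <- data.frame(sample_id = colnames(m),
                       replicate = 1L)
  }
  SpectraSet(m, as.numeric(wn), meta)
}

#' Combine SpectraSets sharing one grid
#'
#' @param ... [SpectraSet-class] objects on identical grids (within
#'   `tolerance` cm-1).
#' @param tolerance maximum absolute grid disagreement.
#' @return a single [SpectraSet-class].
#' @export
bindSpectra <- function(..., tolerance = 1e-6) {
  xs <- list(...)
  stopifnot(length(xs) >= 1)
  wn <- wavenumbers(xs[[1]])
  for (i in seq_along(xs)[-1]) {
    wi <- wavenumbers(xs[[i]])
    if (length(wi) != length(wn) || max(abs(wi - wn)) > tolerance) {
      stop("spectrum set ", i, " is on a different wavenumber grid")
    }
  }
  m <- do.call(cbind, lapply(xs, function(s) assay(s, "absorbance")))
  meta <- do.call(rbind, lapply(xs, sampleData))
  SpectraSet(m, wn, meta)
}

## ---- JCAMP-DX (single block, linear abscissa) ------------------------------

#' Read a minimal JCAMP-DX file
#'
#' Supports a single data block with `##XYDATA=(X++(Y..Y))` on a linear
#' abscissa (FIRSTX/LASTX/NPOINTS with XFACTOR/YFACTOR scaling).
#'
#' @param path file path.
#' @return a list with `x` (wavenumbers), `y` (absorbance), `title`.
#' @export
readJCAMP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getLDR <- function(key, default = NA) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^##", key, "="), "", hit[1], ignore.case = TRUE)
  }
  title <- trimws(getLDR("TITLE", "spectrum"))
  xfac <- as.numeric(getLDR("XFACTOR", "1"))
  yfac <- as.numeric(getLDR("YFACTOR", "1"))
  firstx <- as.numeric(getLDR("FIRSTX"))
  lastx <- as.numeric(getLDR("LASTX"))
  npoints <- as.integer(getLDR("NPOINTS"))
  if (any(is.na(c(firstx, lastx, npoints)))) {
    stop("JCAMP file lacks FIRSTX/LASTX/NPOINTS")
  }
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block found")
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- min(end[end > start[1]], length(lines) + 1L)
  body <- lines[(start[1] + 1L):(end - 1L)]
  ys <- numeric(0)
  for (ln in body) {
    toks <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    if (length(toks) < 2) next
    ys <- c(ys, toks[-1])  # first token is the line's X value
  }
  if (length(ys) != npoints) {
    stop(sprintf("JCAMP NPOINTS=%d but %d Y values read", npoints, length(ys)))
  }
  x <- seq(firstx, lastx, length.out = npoints) * xfac
  list(x = x, y = ys * yfac, title = title)
}

#' Write one spectrum of a SpectraSet as JCAMP-DX
#'
#' @param x a [SpectraSet-class].
#' @param path output path.
#' @param column which spectrum (column index) to export.
#' @return invisibly, `path`.
#' @export
writeJCAMP <- function(x, path, column = 1L) {
  stopifnot(is(x, "SpectraSet"))
  wn <- wavenumbers(x)
  y <- assay(x, "absorbance")[, column]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", colnames(x)[column]),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", wn[1]),
    paste0("##LASTX=", wn[length(wn)]),
    paste0("##NPOINTS=", length(wn)),
    "##XYDATA=(X++(Y..Y))"
  ), con)
  # 6 Y values per line, X prefix
  idx <- seq(1, length(y), by = 6)
  for (i in idx) {
    j <- min(i + 5, length(y))
    writeLines(paste(c(format(wn[i], scientific = FALSE),
                       format(y[i:j], digits = 10)), collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}
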