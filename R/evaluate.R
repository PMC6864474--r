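#' Pipeline configuration for end-to-end runs
#'
#' @param preprocess a [preprocessConfig()].
#' @param scheme a [regionScheme()].
#' @param max_lv maximum latent variables (default 10).
#' @param lv_tolerance parsimony slack for [selectLV()].
#' @param fraction calibration fraction of the sample-level split.
#' @param seed RNG seed for the split (default 2017, the harvest year).
#' @param region fixed list of `c(low, high)` intervals to use instead of
#'   the exhaustive search (`NULL` = search).
#' @param delta_y_set which reference range defines the RER numerator:
#'   `"prediction"` (default), `"calibration"` or `"all"`.
#' @param split_level `"sample"` (grouped, leakage-free default) or
#'   `"spectrum"` (the literal per-spectrum split).
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(preprocess = preprocessConfig(),
                           scheme = regionScheme(), max_lv = 10L,
                           lv_tolerance = 0.02, fraction = 0.70,
                           seed = 2017L, region = NULL,
                           delta_y_set = c("prediction", "calibration", "all"),
                           split_level = c("sample", "spectrum")) {
  structure(list(
    preprocess = preprocess, scheme = scheme, max_lv = as.integer(max_lv),
    lv_tolerance = lv_tolerance, fraction = fraction,
    seed = as.integer(seed), region = region,
    delta_y_set = match.arg(delta_y_set),
    split_level = match.arg(split_level)
  ), class = "PipelineConfig")
}

#' Random calibration/prediction split at the sample level
#'
#' Splits the distinct samples 70/30 (by default) with all replicate
#' spectra of a sample on one side.  The split is stratified by quartile of
#' the sample's reference value so the prediction set spans roughly the
#' calibration range.  Deterministic given `seed`.
#'
#' @param samples character vector of distinct sample ids.
#' @param y reference value per sample (same order), used for
#'   stratification; `NULL` disables stratification.
#' @param fraction calibration fraction in (0, 1).
#' @param seed integer seed.
#' @return list of class `"SplitResult"` with `calibration`, `prediction`
#'   (sample id vectors), `seed`, `fraction`.
#' @export
splitCalibrationPrediction <- function(samples, y = NULL, fraction = 0.70,
                                       seed = 2017L) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("samples must be distinct ids")
  n <- length(samples)
  if (n < 4) stop("need at least 4 samples to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie in (0, 1)")
  ncal <- round(fraction * n)
  if (ncal < 2 || ncal > n - 1) stop("fraction leaves an empty set")
  set.seed(seed)
  strata <- if (is.null(y)) {
    rep(1L, n)
  } else {
    qs <- quantile(y, c(0.25, 0.5, 0.75), type = 7)
    findInterval(y, qs, rightmost.closed = FALSE) + 1L
  }
  idxByStratum <- split(seq_len(n), strata)
  sizes <- lengths(idxByStratum)
  alloc <- floor(fraction * sizes)
  rem <- ncal - sum(alloc)
  if (rem > 0) {
    frac <- fraction * sizes - alloc
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    alloc[bump] <- alloc[bump] + 1L
  } else if (rem < 0) {
    drop <- order(alloc)[seq_len(-rem)]
    alloc[drop] <- pmax(alloc[drop] - 1L, 0L)
  }
  cal <- integer(0)
  for (s in seq_along(idxByStratum)) {
    idx <- idxByStratum[[s]]
    take <- min(alloc[s], length(idx))
    if (take > 0) cal <- c(cal, sample(idx, take))
  }
  # rounding guard: top up / trim at random to hit ncal exactly
  if (length(cal) < ncal) {
    pool <- setdiff(seq_len(n), cal)
    cal <- c(cal, sample(pool, ncal - length(cal)))
  } else if (length(cal) > ncal) {
    cal <- sample(cal, ncal)
  }
  structure(list(
    calibration = samples[sort(cal)],
    prediction = samples[sort(setdiff(seq_len(n), cal))],
    seed = seed, fraction = fraction
  ), class = "SplitResult")
}

#' Classify calibration quality from the range error ratio
#'
#' Models with RER of at least 10 are acceptable for quality control;
#' at least 15, good enough for quantification; below 10, insufficient.
#'
#' @param rer numeric RER (>= 0 or `Inf`).
#' @return character label: `"insufficient"`, `"quality_control"` or
#'   `"quantification"` (vectorized).
#' @export
classifyQuality <- function(rer) {
  if (any(rer < 0, na.rm = TRUE)) stop("RER cannot be negative")
  ifelse(rer >= 15, "quantification",
         ifelse(rer >= 10, "quality_control", "insufficient"))
}

.rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
.r2 <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  1 - sum((obs - pred)^2) / sst
}

#' Figures of merit for a fitted calibration
#'
#' Computes RMSEC/R2C on the calibration rows, carries RMSECV/R2CV from
#' cross-validation, computes RMSEP/R2P on the prediction rows, the range
#' error ratio RER = Delta-y / RMSEP (Delta-y the prediction-set reference
#' range by default) and the RER quality label.
#'
#' @param model a [PLSModel-class] fitted on the calibration rows.
#' @param X_cal,y_cal calibration spectra (already preprocessed and
#'   region-masked) and reference values.
#' @param X_pred,y_pred prediction spectra and reference values.
#' @param rmsecv RMSECV at the model's component count (may be `NA`).
#' @param delta_y_values reference values defining the RER numerator
#'   (defaults to `y_pred`).
#' @param parameter,dataset labels carried into the output row.
#' @return one-row `data.frame` with columns `parameter`, `dataset`,
#'   `region`, `n_lv`, `RMSEC`, `R2C`, `RMSECV`, `R2CV`, `RMSEP`, `R2P`,
#'   `RER`, `quality`.
#' @export
figuresOfMerit <- function(model, X_cal, y_cal, X_pred, y_pred,
                           rmsecv = NA_real_, delta_y_values = y_pred,
                           parameter = NA_character_, dataset = NA) {
  predC <- predict(model, X_cal)
  predP <- predict(model, X_pred)
  rmsec <- .rmse(y_cal, predC)
  rmsep <- .rmse(y_pred, predP)
  r2cv <- if (is.na(rmsecv)) NA_real_ else {
    1 - rmsecv^2 * length(y_cal) / sum((y_cal - mean(y_cal))^2)
  }
  dy <- diff(range(delta_y_values))
  if (rmsep == 0) {
    warning("RMSEP is exactly 0; RER reported as +Inf")
    rer <- Inf
  } else {
    rer <- dy / rmsep
  }
  data.frame(
    parameter = parameter, dataset = dataset, region = model@regionLabel,
    n_lv = model@nLV,
    RMSEC = rmsec, R2C = .r2(y_cal, predC),
    RMSECV = rmsecv, R2CV = r2cv,
    RMSEP = rmsep, R2P = .r2(y_pred, predP),
    RER = rer, quality = classifyQuality(rer),
    stringsAsFactors = FALSE
  )
}

# shared plumbing: filter to a design, align, preprocess, split, optimize
# on calibration rows only, final fit on calibration rows
.fitDesign <- function(spectra, reference, design, parameter, config) {
  ds <- buildDataset(spectra, reference, design)
  al <- alignReference(ds$spectra, ds$reference, parameter)
  pp <- preprocessChain(ds$spectra, config$preprocess)
  samples <- unique(al$groups)
  ySample <- al$y[match(samples, al$groups)]
  if (config$split_level == "spectrum") {
    rowIds <- paste0("row", seq_along(al$y))
    split <- splitCalibrationPrediction(rowIds, al$y, config$fraction,
                                        config$seed)
    calRows <- rowIds %in% split$calibration
  } else {
    split <- splitCalibrationPrediction(samples, ySample, config$fraction,
                                        config$seed)
    calRows <- al$groups %in% split$calibration
  }
  Xc <- pp$X[calRows, , drop = FALSE]
  yc <- al$y[calRows]
  gc_ <- al$groups[calRows]
  if (is.null(config$region)) {
    opt <- optimizeModel(Xc, yc, gc_, pp$wavenumbers, config$scheme,
                         config$max_lv, config$lv_tolerance,
                         config$preprocess)
    model <- opt$model
    rmsecv <- opt$report$rmsecv[opt$winner]
    report <- opt$report
  } else {
    mask <- regionMask(pp$wavenumbers, config$region)
    curve <- suppressWarnings(loocv(Xc[, mask, drop = FALSE], yc, gc_,
                                    config$max_lv))
    k <- selectLV(curve, config$lv_tolerance)
    model <- fitPLS(Xc[, mask, drop = FALSE], yc, k,
                    wavenumbers = pp$wavenumbers[mask],
                    region = config$region,
                    regionLabel = .regionLabel(config$region),
                    preprocess = config$preprocess)
    rmsecv <- curve[k]
    report <- NULL
  }
  list(model = model, rmsecv = rmsecv, report = report, split = split,
       X = pp$X, wavenumbers = pp$wavenumbers, y = al$y,
       groups = al$groups, calRows = calRows, design = ds$design)
}

#' Run the full pipeline for one data-set design
#'
#' Filter to the design, split samples into calibration and prediction
#' sets, preprocess, optimize spectral region and component count by
#' grouped LOOCV on the calibration rows only, fit the final model on the
#' calibration rows and report the figures of merit.
#'
#' @param spectra a [SpectraSet-class].
#' @param reference a ReferenceTable `data.frame`.
#' @param design a [datasetDesign()] or id in 1..6.
#' @param parameter `"TPC"`, `"TFC"` or `"TAC"`.
#' @param config a [pipelineConfig()].
#' @param details return the fitted model and split alongside the row.
#' @return a one-row `data.frame` of figures of merit (see
#'   [figuresOfMerit()]); with `details = TRUE`, a list with `fom`,
#'   `model`, `split`, `report`.
#' @export
runDesign <- function(spectra, reference, design, parameter,
                      config = pipelineConfig(), details = FALSE) {
  fit <- .fitDesign(spectra, reference, design, parameter, config)
  mask <- regionMask(fit$wavenumbers, fit$model@region)
  Xm <- fit$X[, mask, drop = FALSE]
  cal <- fit$calRows
  dyv <- switch(config$delta_y_set,
                prediction = fit$y[!cal],
                calibration = fit$y[cal],
                all = fit$y)
  fom <- figuresOfMerit(fit$model, Xm[cal, , drop = FALSE], fit$y[cal],
                        Xm[!cal, , drop = FALSE], fit$y[!cal],
                        rmsecv = fit$rmsecv, delta_y_values = dyv,
                        parameter = parameter,
                        dataset = fit$design$id)
  if (!details) return(fom)
  list(fom = fom, model = fit$model, split = fit$split, report = fit$report,
       fit = fit)
}

#' Cross-design transferability matrix
#'
#' Entry (i, j) applies the calibration trained under design i's protocol
#' (its own split, region search and component selection) to the samples of
#' design j.  Diagonal entries reduce to [runDesign()] (evaluation on
#' design i's own prediction subset); off-diagonal entries evaluate on all
#' of design j's samples, with the RER range taken from the evaluated rows.
#'
#' @param spectra a [SpectraSet-class].
#' @param reference a ReferenceTable `data.frame`.
#' @param designs vector of design ids (or list of [datasetDesign()]).
#' @param parameter `"TPC"`, `"TFC"` or `"TAC"`.
#' @param config a [pipelineConfig()].
#' @return `data.frame` with one row per (train, eval) pair: columns
#'   `train_design`, `eval_design` plus the figures-of-merit columns
#'   (RMSEC/R2C/RMSECV/R2CV refer to the training design's calibration).
#' @export
transferabilityMatrix <- function(spectra, reference, designs = 1:6,
                                  parameter, config = pipelineConfig()) {
  if (!is.list(designs)) designs <- lapply(designs, datasetDesign)
  if (length(designs) < 2) stop("need at least 2 designs")
  rows <- list()
  for (i in seq_along(designs)) {
    di <- designs[[i]]
    fit <- tryCatch(.fitDesign(spectra, reference, di, parameter, config),
                    error = function(e) NULL)
    if (is.null(fit)) next   # empty design: row marked absent
    for (j in seq_along(designs)) {
      dj <- designs[[j]]
      if (identical(di$id, dj$id)) {
        mask <- regionMask(fit$wavenumbers, fit$model@region)
        Xm <- fit$X[, mask, drop = FALSE]
        cal <- fit$calRows
        fom <- figuresOfMerit(fit$model, Xm[cal, , drop = FALSE],
                              fit$y[cal], Xm[!cal, , drop = FALSE],
                              fit$y[!cal], rmsecv = fit$rmsecv,
                              delta_y_values = fit$y[!cal],
                              parameter = parameter, dataset = dj$id)
      } else {
        dsj <- tryCatch(buildDataset(spectra, reference, dj),
                        error = function(e) NULL)
        if (is.null(dsj)) next
        alj <- alignReference(dsj$spectra, dsj$reference, parameter)
        ppj <- preprocessChain(dsj$spectra, config$preprocess)
        maskj <- regionMask(ppj$wavenumbers, fit$model@region)
        mask <- regionMask(fit$wavenumbers, fit$model@region)
        Xm <- fit$X[, mask, drop = FALSE]
        cal <- fit$calRows
        fom <- figuresOfMerit(fit$model, Xm[cal, , drop = FALSE],
                              fit$y[cal],
                              ppj$X[, maskj, drop = FALSE], alj$y,
                              rmsecv = fit$rmsecv,
                              delta_y_values = alj$y,
                              parameter = parameter, dataset = dj$id)
      }
      fom$train_design <- di$id
      fom$eval_design <- dj$id
      rows[[length(rows) + 1L]] <- fom
    }
  }
  if (!length(rows)) stop("no design produced a fit")
  out <- do.call(rbind, rows)
  front <- c("train_design", "eval_design")
  out[, c(front, setdiff(colnames(out), front))]
}
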