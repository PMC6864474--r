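#' Spectral region scheme (five base windows)
#'
#' The model search divides the working range into five base windows that
#' are tested separately or combined.  Default boundaries (cm-1, closed
#' intervals): 10000--7501, 7500--6316, 6315--5390, 5389--4926, 4925--4073;
#' the third and fifth windows are the two informative ranges for leaf
#' antioxidant calibration.
#'
#' @param boundaries list of `c(low, high)` closed intervals, highest
#'   wavenumbers first; must be non-overlapping and lie within
#'   10000--4000 cm-1 unless `validate = FALSE`.
#' @param validate check the five-window convention.
#' @return a list of class `"RegionScheme"` with element `regions`.
#' @export
regionScheme <- function(boundaries = list(c(7501, 10000), c(6316, 7500),
                                           c(5390, 6315), c(4926, 5389),
                                           c(4073, 4925)),
                         validate = TRUE) {
  regions <- lapply(boundaries, function(b) sort(as.numeric(b)))
  if (validate) {
    for (b in regions) {
      if (b[1] >= b[2]) stop("each interval needs low < high")
    }
    n <- length(regions)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (regions[[i]][1] <= regions[[j]][2] &&
            regions[[j]][1] <= regions[[i]][2]) {
          stop("base regions must not overlap")
        }
      }
    }
  }
  structure(list(regions = regions), class = "RegionScheme")
}

.regionLabel <- function(intervals) {
  if (!length(intervals)) return("full spectrum")
  paste(vapply(intervals, function(b) sprintf("%g-%g", b[2], b[1]),
               character(1)), collapse = " and ")
}

#' All non-empty combinations of the base regions
#'
#' Enumerates the `2^n - 1` non-empty subsets of the scheme's base regions
#' in binary counting order (subset `i` contains region `j` iff bit `j` of
#' `i` is set), each as a list of closed intervals sorted by descending
#' wavenumber.
#'
#' @param scheme a [regionScheme()].
#' @return a list; each element has fields `members` (integer indices),
#'   `intervals`, `label`.
#' @export
enumerateRegionCombinations <- function(scheme = regionScheme()) {
  n <- length(scheme$regions)
  out <- vector("list", 2^n - 1)
  for (i in seq_len(2^n - 1)) {
    members <- which(bitwAnd(i, 2^(seq_len(n) - 1)) > 0)
    ivs <- scheme$regions[members]
    ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 2), decreasing = TRUE)]
    out[[i]] <- list(members = members, intervals = ivs,
                     label = .regionLabel(ivs))
  }
  out
}

#' Column mask for a set of spectral intervals
#'
#' @param wavenumbers grid (cm-1).
#' @param intervals list of `c(low, high)` closed intervals; empty list
#'   selects everything.
#' @return logical vector over the grid.
#' @export
regionMask <- function(wavenumbers, intervals) {
  if (!length(intervals)) return(rep(TRUE, length(wavenumbers)))
  mask <- rep(FALSE, length(wavenumbers))
  for (b in intervals) {
    mask <- mask | (wavenumbers >= b[1] & wavenumbers <= b[2])
  }
  mask
}

#' Exhaustive region-combination and latent-variable optimization
#'
#' For each non-empty combination of the scheme's base regions the columns
#' of `X` are masked to the combination, grouped LOOCV is run, the
#' component count is chosen by the parsimony rule, and the attained RMSECV
#' is recorded.  The winner is the combination with the lowest RMSECV at
#' its selected component count; exact ties are broken by fewer intervals,
#' then fewer latent variables, then enumeration order.
#'
#' @param X preprocessed spectral matrix (rows = spectra).
#' @param y response vector.
#' @param groups sample ids per row (grouped LOOCV).
#' @param wavenumbers grid labelling the columns of `X`.
#' @param scheme a [regionScheme()].
#' @param max_lv maximum component count.
#' @param lv_tolerance parsimony slack for [selectLV()].
#' @param preprocess the upstream [preprocessConfig()], stored in the
#'   winning model as metadata.
#' @return list with `model` (the winning [PLSModel-class] refitted on all
#'   rows), `report` (data.frame: one row per combination with
#'   `combination`, `label`, `n_intervals`, `n_lv`, `rmsecv`; combinations
#'   that could not be evaluated carry `NA` and are excluded from
#'   selection), `winner` (row index into `report`).
#' @export
optimizeModel <- function(X, y, groups, wavenumbers, scheme = regionScheme(),
                          max_lv = 10L, lv_tolerance = 0.02,
                          preprocess = preprocessConfig()) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(wavenumbers))
  combos <- enumerateRegionCombinations(scheme)
  rows <- list()
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    mask <- regionMask(wavenumbers, cb$intervals)
    naRow <- function(why) {
      warning("combination '", cb$label, "' ", why, "; excluded from selection")
      data.frame(combination = i, label = cb$label,
                 n_intervals = length(cb$intervals),
                 n_lv = NA_integer_, rmsecv = NA_real_)
    }
    rows[[i]] <- if (!any(mask)) {
      naRow("has no surviving columns")
    } else {
      Xi <- X[, mask, drop = FALSE]
      curve <- tryCatch(suppressWarnings(loocv(Xi, y, groups, max_lv)),
                        error = function(e) NULL)
      if (is.null(curve) || all(is.na(curve))) {
        naRow("could not be cross-validated (degenerate data)")
      } else {
        k <- selectLV(curve, lv_tolerance)
        data.frame(combination = i, label = cb$label,
                   n_intervals = length(cb$intervals),
                   n_lv = k, rmsecv = curve[k])
      }
    }
  }
  report <- do.call(rbind, rows)
  if (all(is.na(report$rmsecv))) {
    stop("no region combination could be evaluated")
  }
  # combinations whose RMSECV differs from the best by less than numerical
  # noise (1e-8 of the response range) are treated as tied; ties resolve to
  # fewer intervals, then fewer latent variables, then enumeration order
  tieEps <- 1e-8 * diff(range(y))
  best <- min(report$rmsecv, na.rm = TRUE)
  tied <- which(!is.na(report$rmsecv) & report$rmsecv <= best + tieEps)
  ord <- tied[order(report$n_intervals[tied], report$n_lv[tied],
                    report$combination[tied])]
  winner <- ord[1]
  cb <- combos[[report$combination[winner]]]
  mask <- regionMask(wavenumbers, cb$intervals)
  model <- fitPLS(X[, mask, drop = FALSE], y, report$n_lv[winner],
                  wavenumbers = wavenumbers[mask], region = cb$intervals,
                  regionLabel = cb$label, preprocess = preprocess)
  list(model = model, report = report, winner = winner)
}
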