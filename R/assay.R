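#' Fit a standard calibration curve
#'
#' Ordinary least-squares line `response = slope * concentration +
#' intercept` through the standard levels (gallic acid for TPC, catechin
#' for TFC, Trolox for TAC).
#'
#' @param levels standard concentrations (>= 2 distinct values).
#' @param responses measured absorbances, same length.
#' @param standard name of the standard compound.
#' @param units concentration units of the standards.
#' @return list of class `"CalibrationCurve"` with `slope`, `intercept`,
#'   `standard`, `units`, `residuals`, `r_squared`.
#' @export
fitStandardCurve <- function(levels, responses, standard = "standard",
                             units = "mg/L") {
  stopifnot(length(levels) == length(responses))
  if (length(unique(levels)) < 2) {
    stop("need at least 2 distinct standard levels")
  }
  fit <- lm(responses ~ levels)
  slope <- unname(coef(fit)[2])
  if (slope == 0) stop("degenerate standard curve: slope is 0")
  structure(list(
    slope = slope, intercept = unname(coef(fit)[1]),
    standard = standard, units = units,
    residuals = unname(fit$residuals),
    r_squared = 1 - sum(fit$residuals^2) /
      sum((responses - mean(responses))^2)
  ), class = "CalibrationCurve")
}

#' Absorbance to concentration via a standard curve
#'
#' @param curve a [fitStandardCurve()] result.
#' @param absorbance measured absorbances.
#' @return concentrations in the curve's units.
#' @export
curveConcentration <- function(curve, absorbance) {
  (absorbance - curve$intercept) / curve$slope
}

#' Extraction and dilution specification
#'
#' Defaults follow the assay protocol: 50 mg of air-dried milled leaf
#' extracted in 20 mL of 50/50 ethanol/water, with the extract diluted 50x
#' (TPC), 10x (TFC) and 50x (TAC) before the plate assays.
#'
#' @param leaf_mass_g leaf mass in grams.
#' @param solvent_volume_L extraction volume in litres.
#' @param dilution named vector of dilution factors per parameter.
#' @return list of class `"ExtractionSpec"`.
#' @export
extractionSpec <- function(leaf_mass_g = 0.050, solvent_volume_L = 0.020,
                           dilution = c(TPC = 50, TFC = 10, TAC = 50)) {
  if (any(c(leaf_mass_g, solvent_volume_L, dilution) <= 0)) {
    stop("all extraction quantities must be positive")
  }
  structure(list(leaf_mass_g = leaf_mass_g,
                 solvent_volume_L = solvent_volume_L,
                 dilution = dilution), class = "ExtractionSpec")
}

#' Convert a diluted assay concentration to per-gram leaf content
#'
#' `content = diluted_conc * dilution * volume / mass`, giving mg
#' equivalent per g dry leaf (TPC, TFC) or mM Trolox per g dry leaf (TAC).
#'
#' @param diluted_conc concentration measured in the diluted assay solution
#'   (mg/L for TPC/TFC, mM for TAC); must be >= 0.
#' @param parameter `"TPC"`, `"TFC"` or `"TAC"`.
#' @param spec an [extractionSpec()].
#' @return numeric per-gram content.
#' @examples
#' concentrationToContent(10, "TPC")  # 10 * 50 * 0.020 / 0.050 = 200
#' @export
concentrationToContent <- function(diluted_conc, parameter,
                                   spec = extractionSpec()) {
  if (!(parameter %in% names(spec$dilution))) {
    stop("unknown parameter '", parameter, "'")
  }
  if (any(diluted_conc < 0)) stop("concentration cannot be negative")
  diluted_conc * unname(spec$dilution[parameter]) *
    spec$solvent_volume_L / spec$leaf_mass_g
}

#' Summary statistics over a reference table
#'
#' Minimum, maximum, range and the argmin/argmax cells of a parameter's
#' values, computed from the table cells (never hard-coded), with optional
#' season/region/cultivar filters; missing cells are simply absent rows.
#'
#' @param reference a ReferenceTable `data.frame` (e.g.
#'   [referenceFixture()]).
#' @param parameter parameter to summarize.
#' @param seasons,regions,cultivars optional filters.
#' @return list with `n`, `min`, `max`, `range`, `argmin`, `argmax`
#'   (one-row data.frames), `by_season`, `by_region` (mean per group).
#' @export
summarizeTable <- function(reference, parameter, seasons = NULL,
                           regions = NULL, cultivars = NULL) {
  df <- reference[reference$parameter == parameter, , drop = FALSE]
  if (!is.null(seasons)) df <- df[df$season %in% seasons, , drop = FALSE]
  if (!is.null(regions)) df <- df[df$region %in% regions, , drop = FALSE]
  if (!is.null(cultivars)) df <- df[df$cultivar %in% cultivars, , drop = FALSE]
  if (!nrow(df)) stop("no cells left after filtering")
  imin <- which.min(df$mean); imax <- which.max(df$mean)
  cols <- c("cultivar", "region", "season", "mean", "sd")
  list(
    n = nrow(df),
    min = df$mean[imin], max = df$mean[imax],
    range = c(df$mean[imin], df$mean[imax]),
    argmin = df[imin, cols],
    argmax = df[imax, cols],
    by_season = vapply(split(df$mean, df$season), mean, numeric(1)),
    by_region = vapply(split(df$mean, df$region), mean, numeric(1))
  )
}

#' Welch two-sample comparison from summary statistics
#'
#' Welch's t statistic with Welch-Satterthwaite degrees of freedom,
#' computed from group means, SDs and sizes (the form available when only
#' the published mean +/- SD of quadruplicate assays is known).  Degenerate
#' inputs (both SDs zero) return p = 1 for equal means and p = 0 otherwise.
#'
#' @param mean_a,sd_a,n_a first group summary (n >= 2, sd >= 0).
#' @param mean_b,sd_b,n_b second group summary.
#' @param alpha significance level for the verdict.
#' @param bonferroni optional number of comparisons; when given, alpha is
#'   divided by it.
#' @return list with `statistic`, `df`, `p_value`, `significant`.
#' @export
compareGroups <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                          alpha = 0.05, bonferroni = NULL) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (!is.null(bonferroni)) alpha <- alpha / bonferroni
  if (sd_a == 0 && sd_b == 0) {
    p <- if (mean_a == mean_b) 1 else 0
    return(list(statistic = if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf,
                df = NA_real_, p_value = p, significant = p < alpha))
  }
  se2a <- sd_a^2 / n_a
  se2b <- sd_b^2 / n_b
  tstat <- (mean_a - mean_b) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (n_a - 1) + se2b^2 / (n_b - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(statistic = tstat, df = df, p_value = p, significant = p < alpha)
}
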