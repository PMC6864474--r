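#' The six canonical season/region data-set designs
#'
#' The calibration study analysed its spectra in six nested data sets:
#' \enumerate{
#'   \item all leaves (spring/fall/winter, RA/RB/RC);
#'   \item one region, all seasons (spring/fall/winter, RA);
#'   \item spring leaves, all regions (RA/RB/RC);
#'   \item spring leaves, one region (RA);
#'   \item fall leaves (RA);
#'   \item winter leaves (RA).
#' }
#'
#' @param id design id in 1..6, or `NULL` to supply custom filters.
#' @param seasons,regions custom filters (character vectors) used when
#'   `id` is `NULL`.
#' @return a list of class `"DataSetDesign"` with fields `id`, `seasons`,
#'   `regions`.
#' @export
datasetDesign <- function(id = NULL, seasons = NULL, regions = NULL) {
  canon <- list(
    `1` = list(seasons = c("spring", "fall", "winter"),
               regions = c("RA", "RB", "RC")),
    `2` = list(seasons = c("spring", "fall", "winter"), regions = "RA"),
    `3` = list(seasons = "spring", regions = c("RA", "RB", "RC")),
    `4` = list(seasons = "spring", regions = "RA"),
    `5` = list(seasons = "fall", regions = "RA"),
    `6` = list(seasons = "winter", regions = "RA")
  )
  if (!is.null(id)) {
    id <- as.integer(id)
    if (!(id %in% 1:6)) stop("design id must be in 1..6")
    d <- canon[[as.character(id)]]
    return(structure(list(id = id, seasons = d$seasons, regions = d$regions),
                     class = "DataSetDesign"))
  }
  if (is.null(seasons) || is.null(regions)) {
    stop("supply either a design id or both custom filters")
  }
  structure(list(id = NA_integer_, seasons = seasons, regions = regions),
            class = "DataSetDesign")
}

#' @export
print.DataSetDesign <- function(x, ...) {
  cat(sprintf("DataSetDesign %s: seasons {%s}, regions {%s}\n",
              ifelse(is.na(x$id), "custom", x$id),
              paste(x$seasons, collapse = ", "),
              paste(x$regions, collapse = ", ")))
  invisible(x)
}

#' Filter spectra and reference values by a data-set design
#'
#' Retains only the samples whose `season` and `region` match the design,
#' keeping spectra and reference rows aligned.  Either argument may be
#' `NULL` to filter just the other.
#'
#' @param spectra a [SpectraSet-class] or `NULL`.
#' @param reference a ReferenceTable `data.frame` or `NULL`.
#' @param design a [datasetDesign()] or a design id in 1..6.
#' @return list with elements `spectra`, `reference`, `design`.
#' @export
buildDataset <- function(spectra = NULL, reference = NULL, design) {
  if (!inherits(design, "DataSetDesign")) design <- datasetDesign(design)
  out <- list(spectra = NULL, reference = NULL, design = design)
  if (!is.null(spectra)) {
    stopifnot(is(spectra, "SpectraSet"))
    cd <- colData(spectra)
    keep <- cd$season %in% design$seasons & cd$region %in% design$regions
    if (!any(keep)) {
      stop("design ", design$id, " retains no spectra (degenerate design)")
    }
    out$spectra <- spectra[, keep]
  }
  if (!is.null(reference)) {
    keep <- reference$season %in% design$seasons &
      reference$region %in% design$regions
    if (!any(keep)) {
      stop("design ", design$id, " retains no reference rows (degenerate design)")
    }
    out$reference <- reference[keep, , drop = FALSE]
  }
  out
}

#' Align spectra with reference values for one parameter
#'
#' Produces the regression triple: the spectral matrix `X` (one row per
#' replicate spectrum), the reference vector `y` (the sample's assay mean,
#' repeated per replicate) and the grouping vector (sample ids) for grouped
#' cross-validation and sample-level splitting.
#'
#' @param spectra a [SpectraSet-class].
#' @param reference a ReferenceTable `data.frame`.
#' @param parameter one of `"TPC"`, `"TFC"`, `"TAC"` (or any parameter
#'   present in `reference`).
#' @return list with `X` (matrix), `y` (numeric), `groups` (character),
#'   `units` (character scalar).
#' @export
alignReference <- function(spectra, reference, parameter) {
  stopifnot(is(spectra, "SpectraSet"))
  rp <- reference[reference$parameter == parameter, , drop = FALSE]
  if (!nrow(rp)) stop("parameter '", parameter, "' absent from reference table")
  cd <- colData(spectra)
  m <- match(cd$sample_id, rp$sample_id)
  if (any(is.na(m))) {
    stop("missing ", parameter, " reference for sample(s): ",
         paste(unique(cd$sample_id[is.na(m)]), collapse = ", "))
  }
  list(
    X = spectraMatrix(spectra),
    y = rp$mean[m],
    groups = as.character(cd$sample_id),
    units = rp$units[1]
  )
}

#' Summarize the plant-level design table
#'
#' Counts cultivars, plants and per-species cultivars from the plants
#' fixture (or a table of the same shape); nothing is hard-coded.
#'
#' @param plants a `data.frame` as returned by [plantsFixture()].
#' @return list with `n_cultivars`, `n_plants`, `per_species` (named integer
#'   vector of cultivar counts), `plants_per_species`.
#' @export
summarizeCounts <- function(plants = plantsFixture()) {
  stopifnot(all(c("cultivar", "species", "n_plants") %in% colnames(plants)))
  list(
    n_cultivars = length(unique(plants$cultivar)),
    n_plants = sum(plants$n_plants),
    per_species = vapply(split(plants$cultivar, plants$species),
                         function(v) length(unique(v)), integer(1)),
    plants_per_species = vapply(split(plants$n_plants, plants$species),
                                sum, numeric(1))
  )
}
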