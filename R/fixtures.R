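#' Packaged reference tables for the blueberry-leaf study
#'
#' Returns the packaged transcriptions of the per-cultivar assay results
#' (mean +/- SD per cultivar x region x season) for one or more parameters.
#' Cells absent in the source tables are simply not present as rows (never
#' imputed).  Seasons follow the collection dates: May = spring,
#' September = fall, December = winter; regions RA (Northern Coast),
#' RB (Northern Inland), RC (South Inland).
#'
#' @param parameters subset of `c("TPC", "TFC", "TAC")`.
#' @return a long `data.frame` (ReferenceTable) with columns `sample_id`,
#'   `cultivar`, `species`, `region`, `season`, `parameter`, `mean`, `sd`,
#'   `units`.
#' @examples
#' tpc <- referenceFixture("TPC")
#' max(tpc$mean)  # 272.8, 'Titan' winter leaves
#' @export
referenceFixture <- function(parameters = PARAMETERS) {
  parameters <- match.arg(parameters, PARAMETERS, several.ok = TRUE)
  out <- lapply(parameters, function(p) {
    path <- system.file("extdata", paste0(tolower(p), ".csv"),
                        package = "leafNIR", mustWork = TRUE)
    df <- read.csv(path, stringsAsFactors = FALSE)
    df$parameter <- p
    df$units <- unname(PARAMETER_UNITS[p])
    df$sample_id <- paste(df$cultivar, df$region, df$season, sep = "_")
    df[, c("sample_id", "cultivar", "species", "region", "season",
           "parameter", "mean", "sd", "units")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Packaged plant-level design table
#'
#' One row per cultivar with species, the number of plants included in the
#' study, the harvest months, and berry presence (not recoverable from the
#' published table layout, hence `NA`).
#'
#' @return a `data.frame` with columns `cultivar`, `species`, `n_plants`,
#'   `months`, `berries_present`.
#' @export
plantsFixture <- function() {
  path <- system.file("extdata", "plants.csv", package = "leafNIR",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(berries_present = "character"))
}

#' All fixture tables at once
#'
#' @return list with elements `TPC`, `TFC`, `TAC` (ReferenceTables for one
#'   parameter each) and `plants`.
#' @export
fixtureTables <- function() {
  out <- lapply(PARAMETERS, referenceFixture)
  names(out) <- PARAMETERS
  out$plants <- plantsFixture()
  out
}
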