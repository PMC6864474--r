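#' Simulation configuration for synthetic leaf NIR data
#'
#' Defines the sampling frame (cultivars x regions x seasons with the study's
#' collection plan: region RA sampled in all three seasons, RB and RC in
#' spring only), the wavenumber grid, analyte absorption bands, interferent
#' bands, baseline/scatter/noise scales, reference value ranges and
#' season/region shifts for the synthetic data generator.
#'
#' Analyte bands are placed inside the two informative windows 6315--5390 and
#' 4925--4073 cm-1 so that the exhaustive region search has a recoverable
#' truth, and their window-wise amplitude patterns are chosen so that no
#' single window identifies any one parameter on its own (each parameter
#' shares its band in one window with another parameter); identification
#' requires both windows jointly.
#'
#' @param seed integer RNG seed.
#' @param n_cultivars number of synthetic cultivars (default 27).
#' @param regions region labels (default `c("RA","RB","RC")`).
#' @param seasons season labels (default `c("spring","fall","winter")`).
#' @param region_seasons named list: which seasons each region is sampled in.
#' @param replicates_per_sample replicate spectra per sample (default 5).
#' @param grid_start,grid_end,grid_step wavenumber grid in cm-1
#'   (defaults 10000, 4000, 8; `grid_start > grid_end`).
#' @param analyte_bands named list (TPC/TFC/TAC), each a data.frame with
#'   columns `center`, `width`, `amplitude` (absorbance per unit
#'   concentration).
#' @param interferent_bands data.frame with `center`, `width`, `amplitude`;
#'   defaults place water combination/overtone bands near 5200 and 6900 cm-1.
#' @param baseline_intercept_sd,baseline_slope_sd per-replicate baseline
#'   drift scales (absorbance units).
#' @param scatter_sd per-replicate multiplicative scatter scale (fractional).
#' @param noise_sd additive white noise scale (absorbance units).
#' @param value_ranges named list of `c(min, max)` per parameter; defaults
#'   are the study's observed ranges (TPC 39.6--272.8 mg gallic acid/g,
#'   TFC 41.2--269.1 mg catechin/g, TAC 22.6--124.8 mM Trolox/g).
#' @param season_offset,region_offset named numeric shifts added to the
#'   reference-value means per season/region (winter leaves richer, region
#'   RA richest, as observed in the field data).
#' @param season_baseline named numeric, per-season amplitude of a broad
#'   background band (center 5100 cm-1, width 500) plus an equal flat
#'   intercept; emulates season-specific moisture/background differences that
#'   degrade cross-season calibration transfer.  Default all zero.
#' @param replicate_sd_frac range of the uniform law for per-sample assay
#'   SDs, expressed as a fraction of the mean.
#'
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(
    seed = 2017L,
    n_cultivars = 27L,
    regions = c("RA", "RB", "RC"),
    seasons = c("spring", "fall", "winter"),
    region_seasons = NULL,
    replicates_per_sample = 5L,
    grid_start = 10000, grid_end = 4000, grid_step = 8,
    analyte_bands = NULL,
    interferent_bands = NULL,
    baseline_intercept_sd = 0.02,
    baseline_slope_sd = 0.01,
    scatter_sd = 0.02,
    noise_sd = 0.001,
    value_ranges = list(TPC = c(39.6, 272.8),
                        TFC = c(41.2, 269.1),
                        TAC = c(22.6, 124.8)),
    season_offset = c(spring = 0, fall = -15, winter = 45),
    region_offset = c(RA = 10, RB = -5, RC = -5),
    season_baseline = NULL,
    replicate_sd_frac = c(0.01, 0.03)) {
  if (is.null(region_seasons)) {
    region_seasons <- stats::setNames(
      lapply(seq_along(regions), function(i) {
        if (i == 1L) seasons else seasons[1]
      }), regions)
  }
  if (is.null(analyte_bands)) {
    band <- function(center, width, amplitude) {
      data.frame(center = center, width = width, amplitude = amplitude)
    }
    # window-1 band at 6000 shared TPC/TFC; band at 5700 shared TFC/TAC;
    # window-2 band at 4600 shared TPC/TAC; band at 4300 shared TPC/TFC.
    analyte_bands <- list(
      TPC = band(c(6000, 4600, 4300), c(60, 50, 45), c(1.0, 1.0, 1.0) * 1e-3),
      TFC = band(c(6000, 5700, 4300), c(60, 55, 45), c(1.0, 1.0, 1.0) * 1e-3),
      TAC = band(c(5700, 4600), c(55, 50), c(1.0, 1.0) * 2e-3)
    )
  }
  if (is.null(interferent_bands)) {
    # water combination/overtone bands dominate leaf NIR spectra; a dominant
    # constant background also keeps the SNV scaling close to linear
    interferent_bands <- data.frame(center = c(6900, 5200),
                                    width = c(150, 120),
                                    amplitude = c(1.0, 1.2))
  }
  if (is.null(season_baseline)) {
    season_baseline <- stats::setNames(rep(0, length(seasons)), seasons)
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    n_cultivars = as.integer(n_cultivars),
    regions = regions, seasons = seasons,
    region_seasons = region_seasons,
    replicates_per_sample = as.integer(replicates_per_sample),
    grid_start = grid_start, grid_end = grid_end, grid_step = grid_step,
    analyte_bands = analyte_bands,
    interferent_bands = interferent_bands,
    baseline_intercept_sd = baseline_intercept_sd,
    baseline_slope_sd = baseline_slope_sd,
    scatter_sd = scatter_sd,
    noise_sd = noise_sd,
    value_ranges = value_ranges,
    season_offset = season_offset,
    region_offset = region_offset,
    season_baseline = season_baseline,
    replicate_sd_frac = replicate_sd_frac
  ), class = "SimulationConfig")
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#'
#' @param config a `"SimulationConfig"` list.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validateSimulationConfig <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with(config, {
    if (!(grid_start > grid_end)) stop("grid_start must exceed grid_end")
    if (!(grid_step > 0)) stop("grid_step must be positive")
    if (length(seq(grid_start, grid_end, by = -grid_step)) < 2) {
      stop("wavenumber grid must have at least 2 points")
    }
    allBands <- rbind(do.call(rbind, analyte_bands),
                      interferent_bands[, c("center", "width", "amplitude")])
    if (any(allBands$center > grid_start | allBands$center < grid_end)) {
      stop("all band centers must lie within [grid_end, grid_start]")
    }
    for (p in names(value_ranges)) {
      vr <- value_ranges[[p]]
      if (!(vr[1] < vr[2])) stop("value_ranges must have min < max (", p, ")")
    }
    scales <- c(baseline_intercept_sd, baseline_slope_sd, scatter_sd,
                noise_sd, unlist(replicate_sd_frac))
    if (any(scales < 0)) stop("all SD/scale parameters must be >= 0")
    if (n_cultivars < 1) stop("need at least one cultivar")
  })
  invisible(TRUE)
}

#' Wavenumber grid of a SimulationConfig
#' @param config a `"SimulationConfig"`.
#' @return descending numeric grid in cm-1.
#' @export
simulationGrid <- function(config) {
  seq(config$grid_start, config$grid_end, by = -config$grid_step)
}

.designFrame <- function(config) {
  cultivars <- sprintf("cv%02d", seq_len(config$n_cultivars))
  rows <- list()
  for (r in config$regions) {
    for (s in config$region_seasons[[r]]) {
      rows[[length(rows) + 1L]] <-
        data.frame(cultivar = cultivars, region = r, season = s)
    }
  }
  if (!length(rows)) stop("empty design: no cultivar/season/region combinations")
  df <- do.call(rbind, rows)
  # a V. ashei minority (every 9th cultivar), constant per cultivar
  cvIdx <- match(df$cultivar, cultivars)
  df$species <- ifelse(cvIdx %% 9 == 0, "V. ashei", "V. corymbosum")
  df$plant_id <- paste0("p_", df$cultivar)
  df$sample_id <- paste(df$cultivar, df$region, df$season, sep = "_")
  df
}

#' Simulate per-sample reference assay values
#'
#' One row per sample (cultivar x region x season present under the
#' collection plan) and parameter.  Each cultivar gets a base value drawn
#' uniformly inside the configured range (its stable antioxidant profile);
#' the sample value is the base shifted by the season and region offsets
#' and clipped back to the range, so the same cultivar moves coherently
#' across seasons and regions.  Per-sample assay SDs are a small uniform
#' fraction of the mean.  Deterministic given `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return a long `data.frame` (a ReferenceTable) with columns `sample_id`,
#'   `cultivar`, `species`, `region`, `season`, `plant_id`, `parameter`,
#'   `mean`, `sd`, `units`.
#' @export
simulateReferenceValues <- function(config) {
  validateSimulationConfig(config)
  design <- .designFrame(config)
  set.seed(config$seed)
  out <- list()
  cultivars <- unique(design$cultivar)
  for (p in names(config$value_ranges)) {
    vr <- config$value_ranges[[p]]
    baseByCultivar <- runif(length(cultivars), vr[1], vr[2])
    base <- baseByCultivar[match(design$cultivar, cultivars)]
    shift <- unname(config$season_offset[design$season]) +
      unname(config$region_offset[design$region])
    shift[is.na(shift)] <- 0
    mean_p <- pmin(pmax(base + shift, vr[1]), vr[2])
    sdf <- runif(nrow(design), config$replicate_sd_frac[1],
                 config$replicate_sd_frac[2])
    out[[p]] <- data.frame(
      design[, c("sample_id", "cultivar", "species", "region", "season",
                 "plant_id")],
      parameter = p, mean = mean_p, sd = mean_p * sdf,
      units = unname(PARAMETER_UNITS[p])
    )
  }
  ref <- do.call(rbind, out)
  rownames(ref) <- NULL
  ref
}

.gaussBands <- function(grid, bands) {
  # sum of Gaussian bands evaluated on the grid
  out <- numeric(length(grid))
  for (j in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[j] *
      exp(-(grid - bands$center[j])^2 / (2 * bands$width[j]^2))
  }
  out
}

#' Simulate replicate NIR spectra for a reference table
#'
#' For each sample and replicate, absorbance at wavenumber v is the sum of
#' concentration-scaled analyte Gaussian bands, interferent bands, a linear
#' baseline `alpha + beta * v_norm`, per-season background, multiplicative
#' scatter `(1 + m)` on the chemical signal, and additive white noise; alpha,
#' beta, m and the noise are drawn per replicate from the configured scales.
#' Deterministic given `config$seed`.
#'
#' @param reference a ReferenceTable from [simulateReferenceValues()] (or of
#'   the same shape); all parameters named in `config$analyte_bands` must be
#'   present for every sample.
#' @param config the [simulationConfig()] used for `reference`.
#' @return a [SpectraSet-class] with
#'   `config$replicates_per_sample` spectra per sample.
#' @export
simulateSpectra <- function(reference, config) {
  validateSimulationConfig(config)
  if (!nrow(reference)) stop("reference table is empty")
  grid <- simulationGrid(config)
  nu <- (grid - min(grid)) / (max(grid) - min(grid))
  samples <- unique(reference$sample_id)
  needed <- names(config$analyte_bands)
  wide <- list()
  for (p in needed) {
    rp <- reference[reference$parameter == p, ]
    m <- match(samples, rp$sample_id)
    if (any(is.na(m))) {
      stop("reference rows missing parameter ", p, " for sample(s): ",
           paste(samples[is.na(m)], collapse = ", "))
    }
    wide[[p]] <- rp$mean[m]
  }
  meta1 <- reference[match(samples, reference$sample_id),
                     c("sample_id", "cultivar", "species", "region", "season",
                       "plant_id")]
  shapes <- lapply(config$analyte_bands, .gaussBands, grid = grid)
  interf <- .gaussBands(grid, config$interferent_bands)
  seasonBg <- .gaussBands(grid, data.frame(center = 5100, width = 500,
                                           amplitude = 1))
  R <- config$replicates_per_sample
  set.seed(config$seed + 1L)
  n <- length(samples)
  mat <- matrix(0, nrow = length(grid), ncol = n * R)
  meta <- meta1[rep(seq_len(n), each = R), ]
  meta$replicate <- rep(seq_len(R), times = n)
  for (i in seq_len(n)) {
    chem <- interf
    for (p in needed) chem <- chem + wide[[p]][i] * shapes[[p]]
    sb <- config$season_baseline[meta1$season[i]]
    if (is.na(sb)) sb <- 0
    chem_season <- chem + sb * seasonBg
    for (r in seq_len(R)) {
      alpha <- rnorm(1, 0, config$baseline_intercept_sd)
      beta <- rnorm(1, 0, config$baseline_slope_sd)
      m <- rnorm(1, 0, config$scatter_sd)
      eps <- if (config$noise_sd > 0) {
        rnorm(length(grid), 0, config$noise_sd)
      } else 0
      mat[, (i - 1L) * R + r] <-
        (1 + m) * chem_season + sb + alpha + beta * nu + eps
    }
  }
  rownames(meta) <- NULL
  SpectraSet(mat, grid, meta)
}

#' Generate the default synthetic study (reference values + spectra)
#'
#' Convenience wrapper producing both halves of the synthetic data set.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `reference` and `spectra`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  ref <- simulateReferenceValues(config)
  list(reference = ref, spectra = simulateSpectra(ref, config))
}
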