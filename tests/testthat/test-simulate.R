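test_that("reference simulation is deterministic and range-conserving", {
  cfg <- simulationConfig(seed = 42)
  ref1 <- simulateReferenceValues(cfg)
  ref2 <- simulateReferenceValues(cfg)
  expect_identical(ref1, ref2)

  # one row per sample x parameter; RA carries all seasons, RB/RC spring only
  expect_setequal(unique(ref1$parameter), c("TPC", "TFC", "TAC"))
  expect_equal(nrow(ref1), 3 * (27 * 3 + 27 + 27))

  for (p in c("TPC", "TFC", "TAC")) {
    vr <- cfg$value_ranges[[p]]
    vals <- ref1$mean[ref1$parameter == p]
    expect_true(all(vals >= vr[1] & vals <= vr[2]))
    expect_true(all(ref1$sd[ref1$parameter == p] >= 0))
  }
})

test_that("season offsets shift cultivar means by exactly the offset", {
  cfg <- simulationConfig(
    seed = 7, n_cultivars = 10L, regions = "RA",
    seasons = c("spring", "winter"),
    region_seasons = list(RA = c("spring", "winter")),
    value_ranges = list(TPC = c(0, 1e6), TFC = c(0, 1e6),
                        TAC = c(0, 1e6)),
    season_offset = c(spring = 0, winter = 60),
    region_offset = c(RA = 0)
  )
  ref <- simulateReferenceValues(cfg)
  tpc <- ref[ref$parameter == "TPC", ]
  w <- tpc[tpc$season == "winter", ]
  s <- tpc[tpc$season == "spring", ]
  d <- w$mean[match(s$cultivar, w$cultivar)] - s$mean
  expect_equal(d, rep(60, nrow(s)), tolerance = 1e-12)
})

test_that("an empty design is rejected explicitly", {
  expect_error(
    simulateReferenceValues(simulationConfig(regions = character(0))),
    "empty design"
  )
})

test_that("single-band spectra follow the closed form c * amplitude at the center", {
  a <- 2e-3
  cfg <- singleBandConfig(seed = 3, amplitude = a, center = 6000)
  ref <- simulateReferenceValues(cfg)
  sp <- simulateSpectra(ref, cfg)
  wn <- wavenumbers(sp)
  i0 <- which(wn == 6000)
  tpc <- ref[ref$parameter == "TPC", ]
  cd <- sampleData(sp)
  for (sid in tpc$sample_id) {
    cols <- which(cd$sample_id == sid)
    conc <- tpc$mean[tpc$sample_id == sid]
    peak <- SummarizedExperiment::assay(sp, "absorbance")[i0, cols]
    expect_equal(unname(peak), rep(conc * a, length(cols)), tolerance = 1e-12)
  }
})

test_that("replicates are identical when all stochastic scales are zero", {
  cfg <- cleanConfig(seed = 5, n_cultivars = 4L)
  st <- simulateStudy(cfg)
  m <- SummarizedExperiment::assay(st$spectra, "absorbance")
  cd <- sampleData(st$spectra)
  for (sid in unique(cd$sample_id)) {
    cols <- which(cd$sample_id == sid)
    expect_equal(ncol(m[, cols, drop = FALSE]), 5)
    expect_true(max(abs(m[, cols] - m[, cols[1]])) == 0)
  }
})

test_that("absorbance is linear in concentration for a single analyte", {
  cfg <- singleBandConfig(seed = 9)
  ref <- simulateReferenceValues(cfg)
  sp <- simulateSpectra(ref, cfg)
  m <- SummarizedExperiment::assay(sp, "absorbance")
  cd <- sampleData(sp)
  tpc <- ref[ref$parameter == "TPC", ]
  conc <- tpc$mean[match(cd$sample_id, tpc$sample_id)]
  # at every 20th wavenumber, absorbance / concentration is constant
  for (i in seq(1, nrow(m), by = 20)) {
    ratio <- m[i, ] / conc
    if (max(abs(m[i, ])) < 1e-12) next  # numerically zero far from the band
    expect_lt(diff(range(ratio)) / max(abs(ratio)), 1e-9)
  }
})

test_that("spectra simulation is deterministic and rejects missing parameters", {
  cfg <- tinyConfig(seed = 2)
  ref <- simulateReferenceValues(cfg)
  s1 <- simulateSpectra(ref, cfg)
  s2 <- simulateSpectra(ref, cfg)
  expect_identical(SummarizedExperiment::assay(s1), SummarizedExperiment::assay(s2))

  refNoTac <- ref[ref$parameter != "TAC", ]
  expect_error(simulateSpectra(refNoTac, cfg), "missing parameter TAC")
})

test_that("config invariants are enforced", {
  expect_error(simulationConfig(grid_start = 4000, grid_end = 10000),
               "grid_start")
  expect_error(simulationConfig(grid_step = -8), "grid_step")
  expect_error(simulationConfig(noise_sd = -1), "scale parameters")
  expect_error(
    simulationConfig(value_ranges = list(TPC = c(5, 1), TFC = c(1, 2),
                                         TAC = c(1, 2))),
    "min < max"
  )
  expect_error(
    simulationConfig(analyte_bands = list(
      TPC = data.frame(center = 12000, width = 50, amplitude = 1e-3))),
    "band centers"
  )
  # default grid: 751 points at 8 cm-1 spacing
  expect_length(simulationGrid(simulationConfig()), 751)
})
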