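test_that("SpectraSet round-trips through wide CSV with metadata", {
  cfg <- tinyConfig(seed = 4)
  st <- simulateStudy(cfg)
  d <- withr::local_tempdir()
  p <- file.path(d, "spec.csv")
  writeSpectraCSV(st$spectra, p)
  back <- readSpectra(p, metaPath = file.path(d, "spec_meta.csv"))
  expect_equal(wavenumbers(back), wavenumbers(st$spectra), tolerance = 1e-12)
  expect_equal(spectraMatrix(back), spectraMatrix(st$spectra),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sampleData(back)$sample_id, sampleData(st$spectra)$sample_id)
  expect_equal(sampleData(back)$season, sampleData(st$spectra)$season)

  # column-name parsing works without the sidecar
  back2 <- readSpectra(p)
  expect_equal(sampleData(back2)$sample_id, sampleData(st$spectra)$sample_id)
  expect_equal(sampleData(back2)$replicate, sampleData(st$spectra)$replicate)
})

test_that("a single default-grid spectrum loads as a one-spectrum set", {
  d <- withr::local_tempdir()
  wn <- seq(10000, 4000, by = -8)
  df <- data.frame(w = wn, s1__r1 = rnorm(length(wn)))
  names(df)[1] <- "wavenumber_cm-1"
  p <- file.path(d, "one.csv")
  write.csv(df, p, row.names = FALSE)
  ss <- readSpectra(p)
  expect_s4_class(ss, "SpectraSet")
  expect_equal(ncol(ss), 1)
  expect_equal(nrow(ss), 751)
})

test_that("grid mismatches and bad cells are explicit errors", {
  wn <- seq(10000, 4000, by = -8)
  meta <- data.frame(sample_id = "s", replicate = 1L)
  a <- SpectraSet(matrix(rnorm(751), ncol = 1), wn, meta)
  b <- SpectraSet(matrix(rnorm(376), ncol = 1), seq(10000, 4000, by = -16),
                  meta)
  expect_error(bindSpectra(a, b), "different wavenumber grid")

  d <- withr::local_tempdir()
  p <- file.path(d, "bad.csv")
  writeLines(c("wavenumber_cm-1,s1__r1", "10000,1.0", "9992,oops", "9984,0.5"),
             p)
  expect_error(readSpectra(p), "row 2.*s1__r1")
})

test_that("SpectraSet validity rejects malformed inputs", {
  wn <- seq(10000, 4000, by = -8)
  meta <- data.frame(sample_id = "s", replicate = 1L)
  expect_error(SpectraSet(matrix(c(1, NA), ncol = 1), c(10, 2),
                          meta), "finite")
  # duplicated replicate index within one sample
  meta2 <- data.frame(sample_id = c("s", "s"), replicate = c(1L, 1L))
  expect_error(SpectraSet(matrix(rnorm(4), ncol = 2), c(10, 2), meta2),
               "unique")
  # ascending input grids are reordered, not rejected
  ss <- SpectraSet(matrix(1:2, ncol = 1), c(4000, 10000), meta)
  expect_equal(wavenumbers(ss), c(10000, 4000))
  expect_equal(as.vector(spectraMatrix(ss)), c(2, 1))
})

test_that("dataset designs filter and compose as set algebra demands", {
  cfg <- simulationConfig(seed = 6, n_cultivars = 6L)
  st <- simulateStudy(cfg)

  d1 <- buildDataset(st$spectra, st$reference, 1)
  expect_equal(ncol(d1$spectra), ncol(st$spectra))   # identity
  expect_equal(nrow(d1$reference), nrow(st$reference))

  ids <- function(x) unique(sampleData(x$spectra)$sample_id)
  d2 <- buildDataset(st$spectra, st$reference, 2)
  d3 <- buildDataset(st$spectra, st$reference, 3)
  d4 <- buildDataset(st$spectra, st$reference, 4)
  d5 <- buildDataset(st$spectra, st$reference, 5)
  d6 <- buildDataset(st$spectra, st$reference, 6)
  expect_true(all(ids(d4) %in% ids(d2)))
  expect_true(all(ids(d4) %in% ids(d3)))
  # union of the single-season RA designs is the all-season RA design
  expect_setequal(c(ids(d4), ids(d5), ids(d6)), ids(d2))

  # idempotence
  d4b <- buildDataset(d4$spectra, d4$reference, 4)
  expect_equal(ncol(d4b$spectra), ncol(d4$spectra))
  expect_identical(d4b$reference, d4$reference)

  # a design matching nothing errors
  expect_error(
    buildDataset(d4$spectra, NULL, datasetDesign(seasons = "fall",
                                                 regions = "RC")),
    "no spectra"
  )
  expect_error(datasetDesign(7), "1..6")
})

test_that("alignReference expands samples by replicate and checks coverage", {
  cfg <- tinyConfig(seed = 8)
  st <- simulateStudy(cfg)
  keep <- sampleData(st$spectra)$sample_id %in%
    unique(sampleData(st$spectra)$sample_id)[1:3]
  sp3 <- st$spectra[, keep]
  al <- alignReference(sp3, st$reference, "TPC")
  expect_equal(nrow(al$X), 15)
  expect_length(al$y, 15)
  expect_length(unique(al$groups), 3)
  # y is the sample mean repeated per replicate
  tpc <- st$reference[st$reference$parameter == "TPC", ]
  expect_equal(al$y, tpc$mean[match(al$groups, tpc$sample_id)])

  expect_error(alignReference(sp3, st$reference, "XYZ"), "absent")
  refMissing <- st$reference[st$reference$sample_id != al$groups[1], ]
  expect_error(alignReference(sp3, refMissing, "TPC"), al$groups[1])
})

test_that("JCAMP-DX single-block spectra round-trip", {
  cfg <- tinyConfig(seed = 10)
  st <- simulateStudy(cfg)
  d <- withr::local_tempdir()
  p <- file.path(d, "one.jdx")
  writeJCAMP(st$spectra, p, column = 3L)
  back <- readSpectra(p, format = "jcamp")
  expect_equal(wavenumbers(back), wavenumbers(st$spectra), tolerance = 1e-9)
  expect_equal(as.vector(spectraMatrix(back)),
               as.vector(spectraMatrix(st$spectra)[3, ]), tolerance = 1e-7)
})
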