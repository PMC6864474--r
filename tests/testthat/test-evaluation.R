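test_that("the calibration/prediction split is grouped, sized and seeded", {
  samples <- sprintf("s%02d", 1:10)
  y <- seq(10, 100, length.out = 10)
  sp <- splitCalibrationPrediction(samples, y, fraction = 0.7, seed = 1)
  expect_length(sp$calibration, 7)
  expect_length(sp$prediction, 3)
  expect_length(intersect(sp$calibration, sp$prediction), 0)
  expect_setequal(c(sp$calibration, sp$prediction), samples)

  sp2 <- splitCalibrationPrediction(samples, y, fraction = 0.7, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- splitCalibrationPrediction(samples, y, fraction = 0.7, seed = 2)
  expect_false(identical(sp$calibration, sp3$calibration))

  expect_error(splitCalibrationPrediction(samples, y, fraction = 1.2), "fraction")
  expect_error(splitCalibrationPrediction(samples[1:3], y[1:3]), "at least 4")
  expect_error(splitCalibrationPrediction(c("a", "a", "b", "c")), "distinct")
})

test_that("all replicate spectra of a sample end up on one side of the split", {
  cfg <- tinyConfig(seed = 41)
  st <- simulateStudy(cfg)
  out <- suppressWarnings(runDesign(st$spectra, st$reference, 4, "TPC",
                                    pipelineConfig(max_lv = 4),
                                    details = TRUE))
  both <- intersect(out$split$calibration, out$split$prediction)
  expect_length(both, 0)
  cal <- out$fit$calRows
  expect_setequal(unique(out$fit$groups[cal]), out$split$calibration)
  expect_setequal(unique(out$fit$groups[!cal]), out$split$prediction)
})

test_that("RER classification follows the quality-control thresholds", {
  expect_equal(classifyQuality(9.9), "insufficient")
  expect_equal(classifyQuality(11.2), "quality_control")
  expect_equal(classifyQuality(17.3), "quantification")
  expect_equal(classifyQuality(c(10, 15, Inf)),
               c("quality_control", "quantification", "quantification"))
  expect_error(classifyQuality(-1), "negative")
})

test_that("figures of merit satisfy their defining identities", {
  cfg <- tinyConfig(seed = 42)
  st <- simulateStudy(cfg)
  out <- suppressWarnings(runDesign(st$spectra, st$reference, 4, "TPC",
                                    pipelineConfig(), details = TRUE))
  fom <- out$fom
  al <- alignReference(
    buildDataset(st$spectra, st$reference, 4)$spectra, st$reference, "TPC")
  predIds <- out$split$prediction
  yPred <- al$y[al$groups %in% predIds]
  # RER x RMSEP reproduces the prediction-set reference range exactly
  expect_equal(fom$RER * fom$RMSEP, diff(range(yPred)), tolerance = 1e-10)
  expect_equal(fom$quality, classifyQuality(fom$RER))
  # R2 consistency with the RMSE on the same rows
  yCal <- al$y[al$groups %in% out$split$calibration]
  expect_equal(fom$R2P,
               1 - fom$RMSEP^2 * length(yPred) /
                 sum((yPred - mean(yPred))^2), tolerance = 1e-10)
  expect_equal(fom$R2C,
               1 - fom$RMSEC^2 * length(yCal) /
                 sum((yCal - mean(yCal))^2), tolerance = 1e-10)
  expect_true(all(c(fom$RMSEC, fom$RMSEP, fom$RMSECV) >= 0))
})

test_that("a perfect calibration reports zero RMSEP and infinite RER", {
  set.seed(43)
  t0 <- rnorm(24)
  w <- rnorm(40)
  X <- t0 %*% t(w)
  y <- 4 * t0 + 2
  m <- fitPLS(X, y, 1)
  # evaluate against the model's own predictions: residuals exactly zero
  yPerfect <- predict(m, X[17:24, ])
  expect_warning(
    fom <- figuresOfMerit(m, X[1:16, ], y[1:16], X[17:24, ], yPerfect),
    "RER"
  )
  expect_equal(fom$RMSEP, 0)
  expect_equal(fom$R2P, 1)
  expect_equal(fom$RER, Inf)
  expect_equal(fom$quality, "quantification")
})

test_that("RER is invariant to rescaling the response units", {
  cfg <- tinyConfig(seed = 44)
  st <- simulateStudy(cfg)
  reg <- list(c(5390, 6315), c(4073, 4925))
  pc <- pipelineConfig(region = reg, max_lv = 4)
  r1 <- suppressWarnings(runDesign(st$spectra, st$reference, 4, "TPC", pc))
  ref2 <- st$reference
  sel <- ref2$parameter == "TPC"
  ref2$mean[sel] <- ref2$mean[sel] * 3.7
  # spectra unchanged: rescaling y only (units change, chemistry identical)
  r2 <- suppressWarnings(runDesign(st$spectra, ref2, 4, "TPC", pc))
  expect_equal(r2$RER, r1$RER, tolerance = 1e-8)
  expect_equal(r2$RMSEP, r1$RMSEP * 3.7, tolerance = 1e-8)
})

test_that("runDesign is reproducible and reports a complete row", {
  cfg <- tinyConfig(seed = 45)
  st <- simulateStudy(cfg)
  pc <- pipelineConfig(max_lv = 4)
  r1 <- suppressWarnings(runDesign(st$spectra, st$reference, 4, "TPC", pc))
  r2 <- suppressWarnings(runDesign(st$spectra, st$reference, 4, "TPC", pc))
  expect_identical(r1, r2)
  expect_named(r1, c("parameter", "dataset", "region", "n_lv", "RMSEC",
                     "R2C", "RMSECV", "R2CV", "RMSEP", "R2P", "RER",
                     "quality"))
  expect_equal(r1$dataset, 4L)
})

test_that("the transferability matrix covers every design pair consistently", {
  cfg <- simulationConfig(seed = 46, n_cultivars = 8L)
  st <- simulateStudy(cfg)
  reg <- list(c(5390, 6315), c(4073, 4925))
  pc <- pipelineConfig(region = reg, max_lv = 4)
  tm <- suppressWarnings(
    transferabilityMatrix(st$spectra, st$reference, 4:6, "TPC", pc))
  expect_equal(nrow(tm), 9)
  expect_setequal(unique(tm$train_design), 4:6)
  # the diagonal equals the standalone runs under the same seed
  for (d in 4:6) {
    row <- tm[tm$train_design == d & tm$eval_design == d, ]
    solo <- suppressWarnings(runDesign(st$spectra, st$reference, d, "TPC", pc))
    expect_equal(row$RMSEP, solo$RMSEP, tolerance = 1e-12)
    expect_equal(row$R2P, solo$R2P, tolerance = 1e-12)
  }
})
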