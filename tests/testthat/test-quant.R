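# Calibration, LOD/LOQ, recovery, matrix effect, CV, quantitation.

test_that("a noise-free calibration recovers the generative slope exactly", {
  sc <- coelutionScenario(seed = 31)
  cal <- simulateCalibrationSeries(sc)
  m <- suppressWarnings(fitCalibration(cal, "FA 18:2-OOMxP"))
  # generative area-ratio slope recorded in the ledger
  ledgerSlope <- unique(stats::na.omit(
    groundTruth(cal)$expected_response_slope))
  expect_equal(ledgerSlope, 0.0022, tolerance = 1e-12)
  expect_equal(m@slope, ledgerSlope, tolerance = 1e-6)
  expect_lt(abs(m@intercept), 1e-9)
  expect_gt(m@rSquared, 0.999999)
  expect_identical(m@responseMode, "area_ratio_to_IS")
})

test_that("absolute-area mode recovers the area-scale slope", {
  sc <- coelutionScenario(seed = 32)
  cal <- simulateCalibrationSeries(sc)
  m <- suppressWarnings(
    fitCalibration(cal, "FA 18:2-OOMxP",
                   responseMode = "absolute_area"))
  # area slope = RF * sigma * 60 * sqrt(2*pi), up to 5%-boundary
  # truncation of the integrated Gaussian
  expect_equal(m@slope, 0.0022 * 1e5 * 0.05 * 60 * sqrt(2 * pi),
               tolerance = 0.01)
})

test_that("noisy ten-level calibrations keep R^2 above 0.97", {
  ok <- vapply(1:60, function(s) {
    sc <- coelutionScenario(seed = 4000 + s, noiseSd = 2,
                            replicateCv = 0.05)
    m <- fitCalibration(simulateCalibrationSeries(sc),
                        "FA 18:2-OOMxP")
    m@rSquared >= 0.97 && m@rSquared <= 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("calibration refuses runs with fewer than 4 usable levels", {
  sc <- coelutionScenario(seed = 33)
  cal2 <- simulateCalibrationSeries(sc, levels = c(10, 100))
  expect_error(suppressWarnings(fitCalibration(cal2, "FA 18:2-OOMxP")),
               "insufficient")
  # all levels below LOQ is just as unusable (responses buried in noise)
  scNoisy <- coelutionScenario(seed = 34, noiseSd = 15,
                               scaleUnits = 100)
  calN <- simulateCalibrationSeries(scNoisy,
                                    levels = c(1, 2.5, 5, 10))
  expect_error(fitCalibration(calN, "FA 18:2-OOMxP"), "insufficient")
})

test_that("LOD and LOQ snap to the prepared grid at S/N 3 and 10", {
  # heights: level * 1000; noise ~28.6 -> S/N(0.1) ~ 3.5, S/N(1) ~ 35
  sc <- oneAnalyteScenario(seed = 35, noiseSd = 100 / 3.5,
                           replicateCv = 0)
  cal <- simulateCalibrationSeries(sc, replicates = 3)
  ll <- determineLodLoq(cal, "FA 18:2-OOMxP")
  expect_equal(ll$lod, 0.1)
  expect_equal(ll$loq, 1)

  # with vanishing noise everything is detectable at the lowest level
  sc0 <- oneAnalyteScenario(seed = 36, noiseSd = 0)
  ll0 <- determineLodLoq(simulateCalibrationSeries(sc0),
                         "FA 18:2-OOMxP")
  expect_equal(ll0$lod, min(calibrationLevels()))
  expect_equal(ll0$loq, min(calibrationLevels()))

  # nothing above noise -> above-top-level sentinel
  scZ <- oneAnalyteScenario(seed = 37, trueConcentration = 0,
                            noiseSd = 5)
  llZ <- determineLodLoq(simulateCalibrationSeries(scZ, levels = 0,
                                                   replicates = 3),
                         "FA 18:2-OOMxP")
  expect_identical(llZ$lod, Inf)
  expect_identical(llZ$loq, Inf)
})

test_that("recovery is the spiked-sample / spiked-extract area ratio", {
  expect_equal(computeRecovery(70, 100)$recovery_pct, 70)
  expect_equal(computeRecovery(100, 100)$recovery_pct, 100)
  expect_equal(computeRecovery(0, 100)$recovery_pct, 0)
  expect_error(computeRecovery(50, 0), "> 0")
  r <- computeRecovery(c(68, 70, 72), c(100, 100, 100))
  expect_equal(r$recovery_pct, 70)
  expect_equal(r$sd, sd(c(68, 70, 72)))
})

test_that("matrix effect classifies suppression and enhancement", {
  me <- computeMatrixEffect(91, 100)
  expect_equal(me$matrix_effect_pct, 91)
  expect_identical(me$label, "ion suppression")
  expect_identical(computeMatrixEffect(102, 100)$label,
                   "ion enhancement")
  expect_identical(computeMatrixEffect(100, 100)$label, "none")
  expect_error(computeMatrixEffect(50, 0), "> 0")
})

test_that("validation estimators recover generative recovery and matrix effect", {
  sc <- oneAnalyteScenario(seed = 38, matrixMultiplier = 0.91,
                           recoveryFraction = 0.70,
                           replicateCv = 0.05, noiseSd = 2)
  vs <- simulateValidationSet(sc, replicates = 5)
  out <- summarizeValidation(vs)
  expect_equal(out$recovery_pct, 70, tolerance = 0.1)   # +/- 7 pct pts
  expect_equal(out$matrix_effect_pct, 91, tolerance = 0.1)
  # percentages are invariant under a global intensity rescale
  sc10 <- oneAnalyteScenario(seed = 38, matrixMultiplier = 0.91,
                             recoveryFraction = 0.70,
                             replicateCv = 0.05, noiseSd = 2,
                             responseFactor = 10000,
                             isResponseFactor = 10000,
                             baselineLevel = 500)
  out10 <- summarizeValidation(simulateValidationSet(sc10,
                                                     replicates = 5))
  expect_equal(out10$recovery_pct, out$recovery_pct, tolerance = 0.05)
  expect_equal(out10$matrix_effect_pct, out$matrix_effect_pct,
               tolerance = 0.05)
})

test_that("computeCV matches a two-pass oracle and handles groupings", {
  set.seed(99)
  x <- rlnorm(30, 0, 0.05)
  expect_equal(computeCV(x), 100 * sd(x) / mean(x),
               tolerance = 1e-12)
  expect_equal(computeCV(rep(5, 10)), 0)
  expect_error(computeCV(c(1, 2)), ">= 3")
  expect_error(computeCV(c(-1, 0, 1)), "zero-mean")

  day <- rep(1:3, each = 10)
  intra <- mean(vapply(split(x, day),
                       function(g) 100 * sd(g) / mean(g), numeric(1)))
  expect_equal(computeCV(x, "intraday", day = day), intra,
               tolerance = 1e-12)
  dm <- vapply(split(x, day), mean, numeric(1))
  expect_equal(computeCV(x, "interday", day = day),
               100 * sd(dm) / mean(dm), tolerance = 1e-12)
  expect_error(computeCV(x, "interday", day = rep(1:2, 15)), ">= 3")
  expect_error(computeCV(x, "intraday"), "day label")
})

test_that("measured area CV tracks the generative replicate CV", {
  sc <- oneAnalyteScenario(seed = 39, replicateCv = 0.05, noiseSd = 2)
  set <- simulateCalibrationSeries(sc, levels = 50, replicates = 100)
  pt <- integrateSampleSet(set)
  areas <- pt$area[pt$species == "FA 18:2-OOMxP"]
  cv <- computeCV(areas)
  expect_gt(cv, 4)
  expect_lt(cv, 6)
})

test_that("intra/inter-day CVs from replicate sets stay below 15%", {
  sc <- oneAnalyteScenario(seed = 40, replicateCv = 0.08, noiseSd = 2)
  reps <- simulateReplicates(sc, replicates = 6, days = 3,
                             dayCv = 0.05)
  vs <- simulateValidationSet(sc, replicates = 3)
  out <- summarizeValidation(vs, repSet = reps)
  expect_true(all(c("cv_intraday_pct", "cv_interday_pct")
                  %in% names(out)))
  expect_lt(out$cv_intraday_pct, 15)
  expect_lt(out$cv_interday_pct, 15)
})

test_that("quantitation inverts the calibration", {
  sc <- coelutionScenario(seed = 41)
  m <- suppressWarnings(
    fitCalibration(simulateCalibrationSeries(sc), "FA 18:2-OOMxP"))
  models <- list("FA 18:2-OOMxP" = m)
  rtMap <- retentionTimes(sc)

  s50 <- simulateCalibrationSeries(sc, levels = 50)
  rep <- quantifySample(s50, models, rtMap)
  expect_equal(rep$concentration, 50, tolerance = 0.01)
  expect_identical(rep$flags, "ok")
  expect_identical(rep$units, "pmol/uL_extract")

  # the dilution chain back-calculates to source units (50 -> 100 uL)
  repSrc <- quantifySample(s50, models, rtMap, sourceVolume = 50,
                           finalVolume = 100)
  expect_equal(repSrc$concentration, 100, tolerance = 0.01)
  expect_identical(repSrc$units, "pmol/uL_source")
})

test_that("quantitation grades results against LOD/LOQ", {
  sc <- coelutionScenario(seed = 42)
  m <- suppressWarnings(
    fitCalibration(simulateCalibrationSeries(sc), "FA 18:2-OOMxP"))
  models <- list("FA 18:2-OOMxP" = m)
  rtMap <- retentionTimes(sc)

  # absent analyte -> not detected
  s0 <- simulateCalibrationSeries(sc, levels = 0)
  rep0 <- quantifySample(s0, models, rtMap)
  expect_identical(rep0$flags, "ND")
  expect_true(is.na(rep0$concentration))

  # a response exactly at the LOQ is flagged as such
  sLoq <- simulateCalibrationSeries(sc, levels = m@loq)
  repLoq <- quantifySample(sLoq, models, rtMap)
  expect_match(repLoq$flags, "at_LOQ")
})

test_that("a failing internal standard voids the whole sample", {
  sc <- coelutionScenario(seed = 43)
  m <- suppressWarnings(
    fitCalibration(simulateCalibrationSeries(sc), "FA 18:2-OOMxP"))
  models <- list("FA 18:2-OOMxP" = m)
  rtMap <- retentionTimes(sc)
  s50 <- simulateCalibrationSeries(sc, levels = 50)
  analyteOnly <- list(getTrace(s50, "cal_L01_r1", "FA 18:2-OOMxP"))
  rep <- quantifySample(analyteOnly, models, rtMap)
  expect_true(attr(rep, "qcFailed"))
  expect_identical(rep$flags, "sample_QC_failed_IS")
  expect_true(all(is.na(rep$concentration)))
})

test_that("calibrationTable mirrors the validation-table layout", {
  sc <- coelutionScenario(seed = 44)
  m <- suppressWarnings(
    fitCalibration(simulateCalibrationSeries(sc), "FA 18:2-OOMxP"))
  tab <- calibrationTable(list(m))
  expect_identical(names(tab), c("species", "linearity", "r_squared",
                                 "range", "lod", "loq"))
  expect_match(tab$linearity, "^0.0022x")
})
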