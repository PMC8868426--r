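# Peak detection, integration and S/N estimation.

makeTrace <- function(intensities, times = NULL, species = "X",
                      sampleId = "S") {
  if (is.null(times))
    times <- seq(0, by = 1 / 300, length.out = length(intensities))
  new("ChromatogramTrace", sampleId = sampleId, species = species,
      times = times, intensities = pmax(intensities, 0))
}

test_that("smoothing passes constants, preserves length, checks windows", {
  tr <- makeTrace(rep(100, 50))
  expect_identical(smoothTrace(tr, 5)@intensities, rep(100, 50))
  expect_equal(smoothTrace(tr, 5, "savitzky_golay")@intensities,
               rep(100, 50))
  expect_error(smoothTrace(tr, 4), "odd")
  expect_error(smoothTrace(tr, 1), ">= 3")
  expect_error(smoothTrace(tr, 51), "smaller")
})

test_that("smoothing shifts a Gaussian apex by less than one sample", {
  t <- seq(0, 2, by = 1 / 300)
  y <- 1000 * exp(-0.5 * ((t - 1) / 0.05)^2)
  tr <- makeTrace(y, t)
  sm <- smoothTrace(tr, 5)
  shift <- abs(t[which.max(sm@intensities)] - t[which.max(y)])
  expect_lte(shift, 1 / 300 + 1e-12)
})

test_that("noise-free Gaussian peaks integrate to A*sigma*sqrt(2*pi)", {
  sc <- oneAnalyteScenario(seed = 1, noiseSd = 0, replicateCv = 0)
  tr <- simulateTrace(sc, "FA 18:2-OOMxP")
  rt <- retentionTimes(sc)[["FA 18:2-OOMxP"]]
  pk <- findPeak(tr, c(rt - 0.3, rt + 0.3))
  expect_true(isDetected(pk))
  expect_equal(peakArea(pk), gaussArea(50 * 1000, 0.05),
               tolerance = 0.01)
  # zero-noise S/N is capped with a QC flag, not divided by zero
  expect_equal(snr(pk), 1e6)
  expect_true("zero_noise" %in% qcFlags(pk))
  expect_equal(apexTime(pk), rt, tolerance = 1 / 300)
})

test_that("area and height are invariant under a constant offset", {
  sc <- oneAnalyteScenario(seed = 6, noiseSd = 3)
  tr <- simulateTrace(sc, "FA 18:2-OOMxP")
  rt <- retentionTimes(sc)[["FA 18:2-OOMxP"]]
  shifted <- new("ChromatogramTrace", sampleId = tr@sampleId,
                 species = tr@species, times = tr@times,
                 intensities = tr@intensities + 500)
  pk1 <- findPeak(tr, c(rt - 0.3, rt + 0.3))
  pk2 <- findPeak(shifted, c(rt - 0.3, rt + 0.3))
  expect_equal(peakArea(pk2), peakArea(pk1), tolerance = 1e-6)
  expect_equal(peakHeight(pk2), peakHeight(pk1), tolerance = 1e-6)
})

test_that("area is linear in amplitude across three decades", {
  areas <- vapply(c(0.1, 1, 10, 100), function(conc) {
    sc <- oneAnalyteScenario(seed = 2, noiseSd = 0,
                             trueConcentration = conc)
    tr <- simulateTrace(sc, "FA 18:2-OOMxP")
    rt <- retentionTimes(sc)[["FA 18:2-OOMxP"]]
    peakArea(findPeak(tr, c(rt - 0.3, rt + 0.3)))
  }, numeric(1))
  ratios <- areas / c(0.1, 1, 10, 100)
  expect_lt(max(abs(ratios / ratios[1] - 1)), 0.01)
})

test_that("S/N scales with amplitude and is invariant to axis rescaling", {
  snrAt <- function(conc, seed) {
    sc <- oneAnalyteScenario(seed = seed, noiseSd = 20,
                             trueConcentration = conc,
                             replicateCv = 0)
    tr <- simulateTrace(sc, "FA 18:2-OOMxP")
    rt <- retentionTimes(sc)[["FA 18:2-OOMxP"]]
    snr(findPeak(tr, c(rt - 0.3, rt + 0.3)))
  }
  # doubling the amplitude doubles S/N (Monte-Carlo over seeds)
  r <- vapply(1:100, function(s) snrAt(2, s) / snrAt(1, s), numeric(1))
  expect_equal(mean(r), 2, tolerance = 0.05)

  # unit rescaling leaves S/N unchanged
  sc <- oneAnalyteScenario(seed = 11, noiseSd = 10)
  tr <- simulateTrace(sc, "FA 18:2-OOMxP")
  rt <- retentionTimes(sc)[["FA 18:2-OOMxP"]]
  pk <- findPeak(tr, c(rt - 0.3, rt + 0.3))
  scaled <- new("ChromatogramTrace", sampleId = "S", species = "X",
                times = tr@times, intensities = tr@intensities * 1000)
  pkI <- findPeak(scaled, c(rt - 0.3, rt + 0.3))
  expect_equal(snr(pkI), snr(pk), tolerance = 1e-9)
  stretched <- new("ChromatogramTrace", sampleId = "S", species = "X",
                   times = tr@times * 2, intensities = tr@intensities)
  pkT <- findPeak(stretched, 2 * c(rt - 0.3, rt + 0.3))
  expect_equal(snr(pkT), snr(pk), tolerance = 1e-9)
})

test_that("a too-narrow window truncates boundaries and is flagged", {
  sc <- oneAnalyteScenario(seed = 3, noiseSd = 0)
  tr <- simulateTrace(sc, "FA 18:2-OOMxP")
  rt <- retentionTimes(sc)[["FA 18:2-OOMxP"]]
  pk <- findPeak(tr, c(rt - 0.05, rt + 0.05))   # +/- 1 sigma
  expect_true("boundary_truncated" %in% qcFlags(pk))
})

test_that("window arguments are validated", {
  sc <- oneAnalyteScenario(seed = 3)
  tr <- simulateTrace(sc, "FA 18:2-OOMxP")
  expect_error(findPeak(tr, c(2, 1)), "min < max")
  expect_error(findPeak(tr, c(-1, 2)), "span")
  expect_error(findPeak(tr, c(1, 99)), "span")
})

test_that("the detector apex agrees with a brute-force scan on 100 seeded traces", {
  # oracle: exhaustive local-maximum scan of an independently smoothed
  # trace (flat baseline cancels in the argmax)
  dt <- 1 / 300
  for (s in 1:100) {
    rtTarget <- 2 + (s %% 10) * 0.05
    sc <- oneAnalyteScenario(
      seed = 1000 + s, noiseSd = 15, trueConcentration = 5,
      retentionTime = c("FA 18:2-OOMxP" = rtTarget,
                        "FA 19:1-OOMxP" = 5))
    tr <- simulateTrace(sc, "FA 18:2-OOMxP")
    win <- c(rtTarget - 0.3, rtTarget + 0.3)
    pk <- findPeak(tr, win)
    smoothed <- stats::filter(tr@intensities, rep(1 / 5, 5))
    idx <- which(tr@times >= win[1] & tr@times <= win[2])
    idx <- idx[!is.na(smoothed[idx])]
    oracleApex <- tr@times[idx[which.max(smoothed[idx])]]
    expect_lte(abs(apexTime(pk) - oracleApex), dt + 1e-12)
  }
})

test_that("integrateSampleSet returns one annotated row per trace", {
  sc <- oneAnalyteScenario(seed = 8, noiseSd = 2)
  cal <- simulateCalibrationSeries(sc, levels = c(1, 10, 100))
  pt <- integrateSampleSet(cal)
  expect_equal(nrow(pt), 6L)
  expect_true(all(c("area", "height", "snr", "detected", "level")
                  %in% names(pt)))
  expect_true(all(pt$detected[pt$species == "FA 19:1-OOMxP"]))
})
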