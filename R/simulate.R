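#' @include transitions.R
NULL

## ---- seeded RNG plumbing ----------------------------------------------

## Evaluate expr under a given seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic sub-seed from a base seed and a string key; keeps the
## result a valid 32-bit integer.
.deriveSeed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

## ---- scenario ---------------------------------------------------------

.DEFAULT_ANALYTES <- c("FA 18:3-OOMxP", "FA 18:2-OOMxP", "FA 18:1-OOMxP",
                       "FA 20:5-OOMxP", "FA 20:4-OOMxP", "FA 22:6-OOMxP",
                       "FA 22:1-OOMxP")
.DEFAULT_IS <- "FA 19:1-OOMxP"

#' The calibration concentration grid
#'
#' The ten-level dilution series used for calibration and LOD/LOQ work:
#' 0.01, 0.1, 1, 2.5, 5, 7.5, 10, 25, 50 and 100 pmol/uL.
#'
#' @return numeric vector of concentrations (pmol/uL).
#' @export
calibrationLevels <- function() {
  c(0.01, 0.1, 1, 2.5, 5, 7.5, 10, 25, 50, 100)
}

#' Construct a simulation scenario
#'
#' Builds a [SimScenario-class] with defaults emulating the assay's
#' study conditions: the seven analyte channels plus the FA 19:1-OOMxP
#' internal standard, retention times evenly spaced over 1.5-5.5 min of
#' a 6-min run (elution-order placeholder; tune per assay), Gaussian
#' peaks of sigma 0.05 min, a 50-count baseline with 5-count white
#' noise, 5 points/second sampling, a 10 pmol/uL internal standard (10
#' uL of 100 uM in a 100 uL final extract), 5% replicate CV and a
#' mandatory seed.
#'
#' Per-species parameters may be given as a single number (recycled) or
#' a named vector; partial named vectors override the default for the
#' named species only.
#'
#' @param species character vector of analyte labels (OOMxP state).
#' @param trueConcentration pmol/uL per analyte (default 50, the
#'   validation spike level).
#' @param responseFactor peak-height counts per pmol/uL (default 1000).
#' @param matrixMultiplier dimensionless ion suppression (<1) or
#'   enhancement (>1) factor (default 1, i.e. neat solution).
#' @param retentionTime,peakWidth minutes; named per species (analytes
#'   and IS).
#' @param peakShape `"gaussian"` (default) or
#'   `"exponentially_modified_gaussian"`.
#' @param tailingTau EMG tail constant, minutes.
#' @param isLabel,isConcentration,isResponseFactor internal-standard
#'   species label, concentration (pmol/uL) and response factor.
#' @param baselineLevel,noiseSd,driftSlope baseline counts, white-noise
#'   SD (counts) and linear drift (counts/min).
#' @param replicateCv lognormal replicate CV (fraction).
#' @param recoveryFraction extraction recovery in (0, 1].
#' @param samplingRate points per second.
#' @param runLength minutes.
#' @param seed mandatory integer RNG seed.
#' @return a validated [SimScenario-class].
#' @examples
#' sc <- SimScenario(seed = 1)
#' sc
#' @export
SimScenario <- function(species = .DEFAULT_ANALYTES,
                        trueConcentration = 50,
                        responseFactor = 1000,
                        matrixMultiplier = 1,
                        retentionTime = NULL,
                        peakWidth = 0.05,
                        peakShape = "gaussian",
                        tailingTau = 0,
                        isLabel = .DEFAULT_IS,
                        isConcentration = 10,
                        isResponseFactor = 1000,
                        baselineLevel = 50,
                        noiseSd = 5,
                        driftSlope = 0,
                        replicateCv = 0.05,
                        recoveryFraction = 0.70,
                        samplingRate = 5,
                        runLength = 6,
                        seed) {
  if (missing(seed))
    stop("a scenario requires an explicit integer seed")
  allSpecies <- unique(c(species, isLabel))
  fillNamed <- function(x, who, default = NULL) {
    out <- stats::setNames(rep(NA_real_, length(who)), who)
    if (!is.null(default)) out[] <- default
    if (is.null(names(x))) {
      out[] <- x
    } else {
      out[names(x)] <- x
    }
    out
  }
  if (is.null(retentionTime))
    retentionTime <- stats::setNames(
      seq(1.5, 5.5, length.out = length(allSpecies)), allSpecies)
  else if (is.null(names(retentionTime)))
    retentionTime <- stats::setNames(
      rep_len(retentionTime, length(allSpecies)), allSpecies)
  else {
    rt <- stats::setNames(
      seq(1.5, 5.5, length.out = length(allSpecies)), allSpecies)
    rt[names(retentionTime)] <- retentionTime
    retentionTime <- rt
  }
  new("SimScenario",
      species = species,
      trueConcentration = fillNamed(trueConcentration, species),
      responseFactor = fillNamed(responseFactor, species),
      matrixMultiplier = fillNamed(matrixMultiplier, allSpecies,
                                   default = 1),
      retentionTime = retentionTime,
      peakWidth = fillNamed(peakWidth, allSpecies, default = 0.05),
      peakShape = peakShape,
      tailingTau = as.numeric(tailingTau),
      isLabel = isLabel,
      isConcentration = as.numeric(isConcentration),
      isResponseFactor = as.numeric(isResponseFactor),
      baselineLevel = as.numeric(baselineLevel),
      noiseSd = as.numeric(noiseSd),
      driftSlope = as.numeric(driftSlope),
      replicateCv = as.numeric(replicateCv),
      recoveryFraction = as.numeric(recoveryFraction),
      samplingRate = as.numeric(samplingRate),
      runLength = as.numeric(runLength),
      seed = as.integer(seed))
}

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario: %d analyte%s + IS (%s), %s peaks, run %g min @ %g pts/s, seed %d\n",
    length(object@species), if (length(object@species) == 1) "" else "s",
    object@isLabel, object@peakShape, object@runLength,
    object@samplingRate, object@seed))
  cat(sprintf(
    "  baseline %g, noise sd %g, drift %g/min, replicate CV %.1f%%, recovery %.0f%%\n",
    object@baselineLevel, object@noiseSd, object@driftSlope,
    100 * object@replicateCv, 100 * object@recoveryFraction))
})

#' Retention-time map of a scenario
#'
#' @param x a [SimScenario-class].
#' @return named numeric vector of retention times (minutes) for all
#'   species including the internal standard.
#' @export
setMethod("retentionTimes", "SimScenario", function(x) x@retentionTime)

#' Read / write scenario files
#'
#' Scenarios are serialized as YAML. A seed is mandatory: scenario
#' files without one are rejected so that every simulation is
#' reproducible.
#'
#' @param path YAML file path.
#' @return `readScenario` returns a [SimScenario-class];
#'   `writeScenario` invisibly returns the path.
#' @export
readScenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("scenario '%s' not found", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$seed))
    stop("scenario file must specify a seed (reproducibility is enforced)")
  args <- y
  for (nm in c("trueConcentration", "responseFactor",
               "matrixMultiplier", "retentionTime", "peakWidth"))
    if (!is.null(args[[nm]]) && is.list(args[[nm]]))
      args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$species)) args$species <- unlist(args$species)
  do.call(SimScenario, args)
}

#' @rdname readScenario
#' @param scenario a [SimScenario-class].
#' @export
writeScenario <- function(scenario, path) {
  y <- list(
    species = as.list(scenario@species),
    trueConcentration = as.list(scenario@trueConcentration),
    responseFactor = as.list(scenario@responseFactor),
    matrixMultiplier = as.list(scenario@matrixMultiplier),
    retentionTime = as.list(scenario@retentionTime),
    peakWidth = as.list(scenario@peakWidth),
    peakShape = scenario@peakShape,
    tailingTau = scenario@tailingTau,
    isLabel = scenario@isLabel,
    isConcentration = scenario@isConcentration,
    isResponseFactor = scenario@isResponseFactor,
    baselineLevel = scenario@baselineLevel,
    noiseSd = scenario@noiseSd,
    driftSlope = scenario@driftSlope,
    replicateCv = scenario@replicateCv,
    recoveryFraction = scenario@recoveryFraction,
    samplingRate = scenario@samplingRate,
    runLength = scenario@runLength,
    seed = scenario@seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

## ---- peak shapes ------------------------------------------------------

## Unit-area peak shapes so that (signal area) = amplitude * sigma *
## sqrt(2*pi) for every shape; for the Gaussian this makes `amplitude`
## the peak height.
.shapeUnitArea <- function(t, rt, sigma, shape, tau) {
  if (shape == "gaussian" || tau < 1e-8)
    return(stats::dnorm(t, mean = rt, sd = sigma))
  ## exponentially modified Gaussian in log space for stability;
  ## erfc(x / sqrt(2)) = 2 * pnorm(-x)
  z <- sigma / tau - (t - rt) / sigma
  logf <- -log(2 * tau) + sigma^2 / (2 * tau^2) - (t - rt) / tau +
    log(2) + stats::pnorm(-z, log.p = TRUE)
  exp(logf)
}

## ---- trace generation -------------------------------------------------

.timeGrid <- function(scenario) {
  seq(0, scenario@runLength, by = 1 / (scenario@samplingRate * 60))
}

## Core generator: one trace at a given noiseless amplitude.
.simTraceCore <- function(scenario, species, amplitude, sampleId,
                          seedKey) {
  t <- .timeGrid(scenario)
  rt <- scenario@retentionTime[[species]]
  sigma <- scenario@peakWidth[[species]]
  signal <- scenario@baselineLevel + scenario@driftSlope * t +
    amplitude * sigma * sqrt(2 * pi) *
      .shapeUnitArea(t, rt, sigma, scenario@peakShape,
                     scenario@tailingTau)
  if (scenario@noiseSd > 0) {
    noise <- .withSeed(.deriveSeed(scenario@seed, seedKey),
                       stats::rnorm(length(t), 0, scenario@noiseSd))
    signal <- signal + noise
  }
  new("ChromatogramTrace", sampleId = sampleId, species = species,
      times = t, intensities = pmax(signal, 0))
}

## Lognormal replicate multiplier with mean 1 and CV = cv.
.replicateMultiplier <- function(cv, seed) {
  if (cv <= 0) return(1)
  sdlog <- sqrt(log(1 + cv^2))
  .withSeed(seed, stats::rlnorm(1, meanlog = -sdlog^2 / 2,
                                sdlog = sdlog))
}

.amplitudeOf <- function(scenario, species, concentration = NULL) {
  if (species == scenario@isLabel) {
    conc <- scenario@isConcentration
    rf <- scenario@isResponseFactor
  } else {
    conc <- if (is.null(concentration))
      scenario@trueConcentration[[species]] else concentration
    rf <- scenario@responseFactor[[species]]
  }
  mm <- scenario@matrixMultiplier[[species]]
  if (is.null(mm) || is.na(mm)) mm <- 1
  conc * rf * mm
}

#' Simulate one SRM chromatogram trace
#'
#' Generates `intensity(t) = baseline + drift * t + amplitude * shape(t)
#' + N(0, noiseSd)` on the scenario's time grid, clamped at zero, with
#' `amplitude = concentration * responseFactor * matrixMultiplier` (the
#' Gaussian-equivalent peak height). The RNG stream is derived from the
#' scenario seed, the sample id and the species, so the same call is
#' reproducible bit-for-bit and independent of call order.
#'
#' @param scenario a [SimScenario-class].
#' @param species species label present in the scenario (analyte or
#'   internal standard).
#' @param sampleId sample identifier (enters the RNG stream key).
#' @param concentration optional concentration override (pmol/uL);
#'   defaults to the scenario's `trueConcentration` (or the IS
#'   concentration for the internal standard).
#' @return a [ChromatogramTrace-class].
#' @examples
#' sc <- SimScenario(seed = 7, noiseSd = 0)
#' tr <- simulateTrace(sc, "FA 18:2-OOMxP")
#' range(tr@times)
#' @export
simulateTrace <- function(scenario, species, sampleId = "S1",
                          concentration = NULL) {
  if (!species %in% c(scenario@species, scenario@isLabel))
    stop(sprintf("species '%s' is not part of the scenario", species))
  amp <- .amplitudeOf(scenario, species, concentration)
  .simTraceCore(scenario, species, amp, sampleId,
                paste("trace", sampleId, species, sep = "|"))
}

## ---- sample sets ------------------------------------------------------

.traceKey <- function(sampleId, species) paste(sampleId, species,
                                               sep = "||")

.makeSampleSet <- function(traces, info, truth, scenario) {
  names(traces) <- .traceKey(info$sample_id, info$species)
  new("SampleSet", traces = traces, info = info, groundTruth = truth,
      scenario = scenario)
}

#' Simulate a calibration dilution series
#'
#' One sample per concentration level (optionally replicated): every
#' analyte scales with the level while the internal standard stays at
#' its constant scenario amount, emulating a standard dilution series
#' prepared with constant IS. Replicate (sample-prep) variability is a
#' lognormal multiplier (mean 1, CV `replicateCv`) drawn once per
#' sample and shared by all of that sample's traces, including the IS
#' -- the variability that internal-standard normalization cancels.
#' The generative ledger is attached as [groundTruth()].
#'
#' @param scenario a [SimScenario-class].
#' @param levels numeric concentrations (pmol/uL); defaults to
#'   [calibrationLevels()].
#' @param replicates replicates per level (default 1).
#' @return a [SampleSet-class]; `info` carries the known design
#'   (`sample_id`, `species`, `level`, `replicate`, `role`).
#' @examples
#' sc <- SimScenario(seed = 11, species = "FA 18:2-OOMxP")
#' cal <- simulateCalibrationSeries(sc)
#' length(sampleIds(cal))
#' @export
simulateCalibrationSeries <- function(scenario,
                                      levels = calibrationLevels(),
                                      replicates = 1L) {
  if (!length(levels) || any(levels < 0))
    stop("'levels' must be non-empty and non-negative")
  allSp <- c(scenario@species, scenario@isLabel)
  traces <- list(); info <- list(); truth <- list()
  for (li in seq_along(levels)) {
    for (ri in seq_len(replicates)) {
      sid <- sprintf("cal_L%02d_r%d", li, ri)
      for (sp in allSp) {
        isIS <- sp == scenario@isLabel
        conc <- if (isIS) scenario@isConcentration else levels[li]
        base <- .amplitudeOf(scenario, sp,
                             if (isIS) NULL else levels[li])
        mult <- .replicateMultiplier(
          scenario@replicateCv,
          .deriveSeed(scenario@seed, paste("repmult", sid, sep = "|")))
        amp <- base * mult
        traces[[length(traces) + 1L]] <-
          .simTraceCore(scenario, sp, amp, sid,
                        paste("trace", sid, sp, sep = "|"))
        sigma <- scenario@peakWidth[[sp]]
        info[[length(info) + 1L]] <- data.frame(
          sample_id = sid, species = sp, role = "calibration",
          level = if (isIS) NA_real_ else levels[li],
          replicate = ri, day = 1L,
          is_internal_standard = isIS)
        mm <- scenario@matrixMultiplier[[sp]]
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, species = sp,
          true_concentration = conc,
          amplitude = amp,
          expected_area = base * sigma * 60 * sqrt(2 * pi),
          response_factor = if (isIS) scenario@isResponseFactor
                            else scenario@responseFactor[[sp]],
          matrix_multiplier = if (is.na(mm)) 1 else mm,
          expected_response_slope = if (isIS) NA_real_ else
            scenario@responseFactor[[sp]] *
              (if (is.na(mm)) 1 else mm) * sigma /
              (scenario@isConcentration * scenario@isResponseFactor *
                 scenario@peakWidth[[scenario@isLabel]]))
      }
    }
  }
  .makeSampleSet(traces, do.call(rbind, info), do.call(rbind, truth),
                 scenario)
}

#' Simulate a recovery / matrix-effect validation triple
#'
#' Generates three sample groups at the scenario's spike concentration:
#' a neat standard (`amplitude = c * RF`), a post-extraction spiked
#' extract (`c * RF * matrixMultiplier`) and a pre-extraction spiked
#' sample (`c * RF * matrixMultiplier * recoveryFraction`). Downstream
#' recovery and matrix-effect estimators must recover the generative
#' fractions.
#'
#' @param scenario a [SimScenario-class]; `matrixMultiplier` and
#'   `recoveryFraction` define the generative truth.
#' @param replicates replicates per group (default 5).
#' @return a [SampleSet-class] with `info$role` in
#'   `c("neat_standard", "spiked_extract", "spiked_sample")`.
#' @export
simulateValidationSet <- function(scenario, replicates = 5L) {
  roles <- c("neat_standard", "spiked_extract", "spiked_sample")
  allSp <- c(scenario@species, scenario@isLabel)
  traces <- list(); info <- list(); truth <- list()
  for (role in roles) {
    for (ri in seq_len(replicates)) {
      sid <- sprintf("%s_r%d", role, ri)
      for (sp in allSp) {
        isIS <- sp == scenario@isLabel
        conc <- if (isIS) scenario@isConcentration
                else scenario@trueConcentration[[sp]]
        rf <- if (isIS) scenario@isResponseFactor
              else scenario@responseFactor[[sp]]
        mm <- scenario@matrixMultiplier[[sp]]
        if (is.na(mm)) mm <- 1
        base <- switch(role,
          neat_standard = conc * rf,
          spiked_extract = conc * rf * mm,
          spiked_sample = conc * rf * mm * scenario@recoveryFraction)
        mult <- .replicateMultiplier(
          scenario@replicateCv,
          .deriveSeed(scenario@seed, paste("repmult", sid, sep = "|")))
        amp <- base * mult
        traces[[length(traces) + 1L]] <-
          .simTraceCore(scenario, sp, amp, sid,
                        paste("trace", sid, sp, sep = "|"))
        info[[length(info) + 1L]] <- data.frame(
          sample_id = sid, species = sp, role = role,
          level = conc, replicate = ri, day = 1L,
          is_internal_standard = isIS)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, species = sp, true_concentration = conc,
          amplitude = amp,
          expected_area = base * scenario@peakWidth[[sp]] * 60 *
            sqrt(2 * pi),
          response_factor = rf, matrix_multiplier = mm,
          recovery_fraction = scenario@recoveryFraction,
          expected_response_slope = NA_real_)
      }
    }
  }
  .makeSampleSet(traces, do.call(rbind, info), do.call(rbind, truth),
                 scenario)
}

#' Simulate replicate measurement sets across days
#'
#' Replicated single-concentration samples for precision studies:
#' `replicates` per day over `days` days, with a per-day lognormal
#' effect of CV `dayCv` shared by all traces of that day (so inter-day
#' CV of daily means targets `dayCv`) on top of the per-replicate CV.
#'
#' @param scenario a [SimScenario-class].
#' @param concentration spike level (pmol/uL); default the scenario's
#'   `trueConcentration`.
#' @param replicates replicates per day.
#' @param days number of days.
#' @param dayCv between-day CV (fraction; default 0.05).
#' @return a [SampleSet-class] with `info$day` set.
#' @export
simulateReplicates <- function(scenario, concentration = NULL,
                               replicates = 6L, days = 1L,
                               dayCv = 0.05) {
  allSp <- c(scenario@species, scenario@isLabel)
  traces <- list(); info <- list(); truth <- list()
  for (d in seq_len(days)) {
    dayMult <- if (days > 1L)
      .replicateMultiplier(dayCv,
                           .deriveSeed(scenario@seed,
                                       paste("daymult", d, sep = "|")))
    else 1
    for (ri in seq_len(replicates)) {
      sid <- sprintf("rep_d%d_r%d", d, ri)
      for (sp in allSp) {
        isIS <- sp == scenario@isLabel
        base <- .amplitudeOf(scenario, sp,
                             if (isIS) NULL else concentration)
        mult <- .replicateMultiplier(
          scenario@replicateCv,
          .deriveSeed(scenario@seed, paste("repmult", sid, sep = "|")))
        amp <- base * dayMult * mult
        traces[[length(traces) + 1L]] <-
          .simTraceCore(scenario, sp, amp, sid,
                        paste("trace", sid, sp, sep = "|"))
        info[[length(info) + 1L]] <- data.frame(
          sample_id = sid, species = sp, role = "replicate",
          level = if (isIS) scenario@isConcentration
                  else if (is.null(concentration))
                    scenario@trueConcentration[[sp]]
                  else concentration,
          replicate = ri, day = d, is_internal_standard = isIS)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, species = sp,
          true_concentration = NA_real_, amplitude = amp,
          expected_area = base * scenario@peakWidth[[sp]] * 60 *
            sqrt(2 * pi),
          response_factor = NA_real_, matrix_multiplier = NA_real_,
          expected_response_slope = NA_real_)
      }
    }
  }
  .makeSampleSet(traces, do.call(rbind, info), do.call(rbind, truth),
                 scenario)
}

## ---- SampleSet accessors ----------------------------------------------

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SampleSet", function(x) x@groundTruth)

#' Sample identifiers of a sample set
#'
#' @param x a [SampleSet-class].
#' @return character vector of unique sample ids, in generation order.
#' @export
setMethod("sampleIds", "SampleSet", function(x) {
  unique(x@info$sample_id)
})

#' Design metadata of a sample set
#'
#' @param x a [SampleSet-class].
#' @return the `info` data.frame (known design: sample, species, role,
#'   nominal level, replicate, day).
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "SampleSet"))
  x@info
}

#' Retrieve one trace from a sample set
#'
#' @param x a [SampleSet-class].
#' @param sampleId sample identifier.
#' @param species species label.
#' @return a [ChromatogramTrace-class].
#' @export
getTrace <- function(x, sampleId, species) {
  stopifnot(is(x, "SampleSet"))
  key <- .traceKey(sampleId, species)
  tr <- x@traces[[key]]
  if (is.null(tr))
    stop(sprintf("no trace for sample '%s', species '%s'", sampleId,
                 species))
  tr
}

setMethod("show", "SampleSet", function(object) {
  cat(sprintf("SampleSet: %d trace%s, %d sample%s (%s), seed %d\n",
              length(object@traces),
              if (length(object@traces) == 1) "" else "s",
              length(sampleIds(object)),
              if (length(sampleIds(object)) == 1) "" else "s",
              paste(unique(object@info$role), collapse = ", "),
              object@scenario@seed))
})

setMethod("show", "ChromatogramTrace", function(object) {
  cat(sprintf(
    "ChromatogramTrace: %s | %s, %d points over %.2f-%.2f min, max %.4g\n",
    object@sampleId, object@species, length(object@times),
    min(object@times), max(object@times), max(object@intensities)))
})
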