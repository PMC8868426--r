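#' @import methods
NULL

.ACYL_STATES <- c("FREE", "OOH", "OOMxP")

#' Fatty acyl species
#'
#' A fatty acyl chain identified by its carbon count and number of
#' double bonds, together with its derivatization state: the free fatty
#' acid (`"FREE"`), its hydroperoxide (`"OOH"`), or the 2-methoxypropene
#' (2-MxP) perketal derivative of the hydroperoxide (`"OOMxP"`).
#' Hydroperoxidation requires at least one double bond (the -OOH group
#' sits allylic to a double bond), so `OOH`/`OOMxP` states demand
#' `doubleBonds >= 1`.
#'
#' @slot carbons integer, number of acyl carbons (>= 2).
#' @slot doubleBonds integer, number of C=C double bonds
#'   (0 <= db <= floor((carbons - 2) / 2)).
#' @slot state character, one of `"FREE"`, `"OOH"`, `"OOMxP"`.
#'
#' @seealso [parseSpecies()], [formulaOf()], [speciesLabel()]
#' @export
setClass("FattyAcylSpecies",
  representation(
    carbons = "integer",
    doubleBonds = "integer",
    state = "character"
  )
)

setValidity("FattyAcylSpecies", function(object) {
  msg <- character()
  if (length(object@carbons) != 1L || is.na(object@carbons) ||
      object@carbons < 2L)
    msg <- c(msg, "'carbons' must be a single integer >= 2")
  if (length(object@doubleBonds) != 1L || is.na(object@doubleBonds) ||
      object@doubleBonds < 0L)
    msg <- c(msg, "'doubleBonds' must be a single non-negative integer")
  if (length(object@state) != 1L || !object@state %in% .ACYL_STATES)
    msg <- c(msg, sprintf("'state' must be one of %s",
                          paste(.ACYL_STATES, collapse = ", ")))
  if (!length(msg)) {
    dbMax <- (object@carbons - 2L) %/% 2L
    if (object@doubleBonds > dbMax)
      msg <- c(msg, sprintf(
        "doubleBonds (%d) exceeds the chemical maximum %d for %d carbons",
        object@doubleBonds, dbMax, object@carbons))
    if (object@state != "FREE" && object@doubleBonds < 1L)
      msg <- c(msg, sprintf(
        "state '%s' requires at least one double bond (allylic -OOH)",
        object@state))
  }
  if (length(msg)) msg else TRUE
})

#' Molecular formula
#'
#' An elemental composition held as a named count vector
#' (e.g. `c(C = 18, H = 34, O = 4)`). Formulas add element-wise with
#' `+`; [monoisotopicMass()] supports the elements C, H, O and Na.
#'
#' @slot counts named numeric vector of non-negative integer element
#'   counts; names are element symbols.
#'
#' @seealso [MolecularFormula()], [formulaOf()], [monoisotopicMass()]
#' @export
setClass("MolecularFormula", representation(counts = "numeric"))

setValidity("MolecularFormula", function(object) {
  cts <- object@counts
  if (length(cts) && (is.null(names(cts)) || any(!nzchar(names(cts)))))
    return("all element counts must be named with element symbols")
  if (anyNA(cts) || any(cts < 0))
    return("element counts must be non-negative")
  if (any(cts != round(cts)))
    return("element counts must be whole numbers")
  if (anyDuplicated(names(cts)))
    return("duplicate element symbols")
  TRUE
})

#' SRM transition
#'
#' One selected-reaction-monitoring channel: a sodiated precursor
#' (`parentMz`) and product ion (`productMz`) for a 2-MxP derivatized
#' fatty acid hydroperoxide, plus the instrument parameters tuned for
#' that channel.
#'
#' @slot species `FattyAcylSpecies` in state `"OOMxP"`.
#' @slot parentMz numeric, precursor m/z (1 decimal, \[M+Na\]+).
#' @slot productMz numeric, product ion m/z (1 decimal).
#' @slot collisionEnergy numeric, collision energy in volts.
#' @slot tubeLens numeric, tube lens offset in volts.
#' @slot polarity character, `"positive"` or `"negative"`.
#' @slot isInternalStandard logical flag.
#'
#' @seealso [buildRegistry()], [predictParentMz()]
#' @export
setClass("SRMTransition",
  representation(
    species = "FattyAcylSpecies",
    parentMz = "numeric",
    productMz = "numeric",
    collisionEnergy = "numeric",
    tubeLens = "numeric",
    polarity = "character",
    isInternalStandard = "logical"
  )
)

setValidity("SRMTransition", function(object) {
  msg <- character()
  if (object@species@state != "OOMxP")
    msg <- c(msg, "transition species must be in state 'OOMxP'")
  if (!(object@parentMz > object@productMz && object@productMz > 0))
    msg <- c(msg, "must satisfy parentMz > productMz > 0")
  if (!object@polarity %in% c("positive", "negative"))
    msg <- c(msg, "'polarity' must be 'positive' or 'negative'")
  if (object@collisionEnergy < 5 || object@collisionEnergy > 50)
    msg <- c(msg, "collisionEnergy must lie in [5, 50] V")
  if (length(msg)) msg else TRUE
})

#' SRM transition registry
#'
#' An ordered collection of [SRMTransition-class] channels with exactly
#' one internal-standard entry. The packaged default registry carries
#' the instrument-optimized assay (8 channels, FA 19:1-OOMxP as IS).
#'
#' @slot entries list of `SRMTransition` objects; species labels unique.
#'
#' @seealso [buildRegistry()], [importTransitionList()],
#'   [validateAgainstRegistry()]
#' @export
setClass("TransitionRegistry", representation(entries = "list"))

setValidity("TransitionRegistry", function(object) {
  if (!length(object@entries))
    return("registry must contain at least one transition")
  if (!all(vapply(object@entries, is, logical(1), "SRMTransition")))
    return("all entries must be SRMTransition objects")
  labs <- vapply(object@entries,
                 function(e) speciesLabel(e@species), character(1))
  if (anyDuplicated(labs))
    return("species labels must be unique")
  nIS <- sum(vapply(object@entries, slot, logical(1),
                    "isInternalStandard"))
  if (nIS != 1L)
    return("registry must flag exactly one internal standard")
  TRUE
})

#' SRM chromatogram trace
#'
#' A time/intensity series for one transition in one sample. Times are
#' minutes and strictly increasing; intensities are non-negative
#' detector counts.
#'
#' @slot sampleId character sample identifier.
#' @slot species character species label of the monitored transition.
#' @slot times numeric vector, minutes, strictly increasing, length >= 10.
#' @slot intensities numeric vector, non-negative, same length as times.
#'
#' @seealso [simulateTrace()], [extractTrace()], [findPeak()]
#' @export
setClass("ChromatogramTrace",
  representation(
    sampleId = "character",
    species = "character",
    times = "numeric",
    intensities = "numeric"
  )
)

setValidity("ChromatogramTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensities))
    msg <- c(msg, "times and intensities must have equal length")
  if (length(object@times) < 10L)
    msg <- c(msg, "a trace needs at least 10 points")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Integrated peak result
#'
#' The outcome of peak detection and integration on one trace:
#' baseline-subtracted height and trapezoidal area (intensity x
#' seconds), apex and boundary times, a robust (MAD-based) noise
#' estimate, the resulting signal-to-noise ratio, the detection
#' decision, and QC flags (`no_peak`, `boundary_truncated`,
#' `zero_noise`, `rt_outside_window`).
#'
#' @slot apexTime numeric, minutes.
#' @slot height numeric, baseline-subtracted apex intensity.
#' @slot area numeric, baseline-subtracted trapezoidal area
#'   (intensity x seconds), >= 0.
#' @slot leftBoundary,rightBoundary numeric, minutes.
#' @slot noiseSd numeric, robust baseline noise estimate.
#' @slot snr numeric, `height / noiseSd` (capped at 1e6 when noise is
#'   numerically zero).
#' @slot detected logical, `TRUE` iff `snr >= minSnr`.
#' @slot qcFlags character vector of QC flags.
#'
#' @seealso [findPeak()]
#' @export
setClass("PeakResult",
  representation(
    apexTime = "numeric",
    height = "numeric",
    area = "numeric",
    leftBoundary = "numeric",
    rightBoundary = "numeric",
    noiseSd = "numeric",
    snr = "numeric",
    detected = "logical",
    qcFlags = "character"
  )
)

setValidity("PeakResult", function(object) {
  msg <- character()
  if (object@area < 0) msg <- c(msg, "area must be >= 0")
  ## undetected peaks report height 0 while keeping the measured S/N
  if (object@detected && object@noiseSd > 0 && is.finite(object@snr) &&
      object@snr < 1e6 &&
      abs(object@snr - object@height / object@noiseSd) >
        1e-8 * max(1, object@snr))
    msg <- c(msg, "snr must equal height/noiseSd when noiseSd > 0")
  if (length(msg)) msg else TRUE
})

#' Calibration model
#'
#' An ordinary-least-squares response-versus-concentration fit for one
#' species, together with the S/N-derived limits of detection and
#' quantification and the fitted linear range. Responses are either the
#' analyte/internal-standard area ratio (default) or absolute areas.
#'
#' @slot species character species label.
#' @slot slope,intercept numeric OLS coefficients (response per
#'   pmol/uL; response).
#' @slot rSquared numeric in \[0, 1\].
#' @slot linearRange numeric length-2, fitted (low, high) pmol/uL.
#' @slot lod,loq numeric, pmol/uL (grid levels; `Inf` sentinel when no
#'   level reaches the S/N threshold).
#' @slot responseMode character, `"area_ratio_to_IS"` or
#'   `"absolute_area"`.
#' @slot nLevels integer, number of levels used in the fit.
#'
#' @seealso [fitCalibration()], [determineLodLoq()], [quantifySample()]
#' @export
setClass("CalibrationModel",
  representation(
    species = "character",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    linearRange = "numeric",
    lod = "numeric",
    loq = "numeric",
    responseMode = "character",
    nLevels = "integer"
  )
)

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (object@slope <= 0)
    msg <- c(msg, "accepted models require slope > 0")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@lod > object@loq)
    msg <- c(msg, "lod must be <= loq")
  if (length(object@linearRange) == 2 && is.finite(object@lod) &&
      object@linearRange[1] < object@lod)
    msg <- c(msg, "linearRange low end must be >= lod")
  if (!object@responseMode %in% c("area_ratio_to_IS", "absolute_area"))
    msg <- c(msg, "unknown responseMode")
  if (length(msg)) msg else TRUE
})

#' Simulation scenario
#'
#' The full parameterization of the synthetic SRM chromatogram
#' generator: per-species true concentrations, response factors
#' (Gaussian-equivalent peak height per pmol/uL), retention times and
#' peak widths, matrix-effect multipliers, internal-standard settings,
#' baseline/noise/drift, replicate CV, recovery fraction, sampling rate
#' and run length, and the mandatory RNG seed.
#'
#' @slot species character vector of analyte labels (OOMxP state).
#' @slot trueConcentration named numeric, pmol/uL per analyte.
#' @slot responseFactor named numeric, peak-height counts per pmol/uL.
#' @slot matrixMultiplier named numeric, dimensionless per analyte.
#' @slot retentionTime named numeric, minutes per species (incl. IS).
#' @slot peakWidth named numeric, Gaussian sigma in minutes.
#' @slot peakShape character, `"gaussian"` or
#'   `"exponentially_modified_gaussian"`.
#' @slot tailingTau numeric, EMG tail constant in minutes (>= 0).
#' @slot isLabel character, internal-standard species label.
#' @slot isConcentration numeric, IS concentration (pmol/uL).
#' @slot isResponseFactor numeric, IS response factor.
#' @slot baselineLevel numeric, counts.
#' @slot noiseSd numeric, additive white-noise SD in counts (>= 0).
#' @slot driftSlope numeric, baseline drift in counts/min.
#' @slot replicateCv numeric in \[0, 1), lognormal replicate CV.
#' @slot recoveryFraction numeric in (0, 1\], extraction recovery.
#' @slot samplingRate numeric, points per second.
#' @slot runLength numeric, minutes.
#' @slot seed integer RNG seed (mandatory).
#'
#' @seealso [SimScenario()], [simulateTrace()],
#'   [simulateCalibrationSeries()], [simulateValidationSet()]
#' @export
setClass("SimScenario",
  representation(
    species = "character",
    trueConcentration = "numeric",
    responseFactor = "numeric",
    matrixMultiplier = "numeric",
    retentionTime = "numeric",
    peakWidth = "numeric",
    peakShape = "character",
    tailingTau = "numeric",
    isLabel = "character",
    isConcentration = "numeric",
    isResponseFactor = "numeric",
    baselineLevel = "numeric",
    noiseSd = "numeric",
    driftSlope = "numeric",
    replicateCv = "numeric",
    recoveryFraction = "numeric",
    samplingRate = "numeric",
    runLength = "numeric",
    seed = "integer"
  )
)

setValidity("SimScenario", function(object) {
  msg <- character()
  sp <- object@species
  need <- function(x, what) {
    if (!all(sp %in% names(x)))
      sprintf("'%s' must be named for every analyte species", what)
    else character()
  }
  msg <- c(msg, need(object@trueConcentration, "trueConcentration"),
           need(object@responseFactor, "responseFactor"),
           need(object@matrixMultiplier, "matrixMultiplier"),
           need(object@retentionTime, "retentionTime"),
           need(object@peakWidth, "peakWidth"))
  if (any(object@trueConcentration < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (any(object@responseFactor <= 0) || object@isResponseFactor <= 0)
    msg <- c(msg, "response factors must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@replicateCv < 0 || object@replicateCv >= 1)
    msg <- c(msg, "replicateCv must lie in [0, 1)")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@runLength <= 0) msg <- c(msg, "runLength must be > 0")
  if (!object@peakShape %in%
      c("gaussian", "exponentially_modified_gaussian"))
    msg <- c(msg, "unknown peakShape")
  if (object@tailingTau < 0) msg <- c(msg, "tailingTau must be >= 0")
  if (object@recoveryFraction <= 0 || object@recoveryFraction > 1)
    msg <- c(msg, "recoveryFraction must lie in (0, 1]")
  rt <- object@retentionTime
  if (any(rt <= 0) || any(rt >= object@runLength))
    msg <- c(msg, "retention times must lie inside (0, runLength)")
  if (any(object@peakWidth <= 0))
    msg <- c(msg, "peak widths must be > 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a scenario requires an explicit integer seed")
  if (length(msg)) msg else TRUE
})

#' Simulated sample set
#'
#' A collection of simulated [ChromatogramTrace-class] objects plus two
#' tables: `info`, the *design* metadata a laboratory would know
#' (sample id, species, role, nominal concentration level, day,
#' replicate), and `groundTruth`, the hidden generative ledger (true
#' amplitudes, expected areas, multipliers). Estimators may read `info`
#' (nominal calibration levels are known by design) but must never read
#' `groundTruth`; it exists so tests can check parameter recovery.
#'
#' @slot traces list of `ChromatogramTrace`.
#' @slot info data.frame of design metadata, one row per trace.
#' @slot groundTruth data.frame generative ledger, one row per trace.
#' @slot scenario the generating `SimScenario`.
#'
#' @seealso [simulateCalibrationSeries()], [simulateValidationSet()],
#'   [groundTruth()], [integrateSampleSet()]
#' @export
setClass("SampleSet",
  representation(
    traces = "list",
    info = "data.frame",
    groundTruth = "data.frame",
    scenario = "SimScenario"
  )
)

setValidity("SampleSet", function(object) {
  if (!all(vapply(object@traces, is, logical(1), "ChromatogramTrace")))
    return("all traces must be ChromatogramTrace objects")
  if (nrow(object@info) != length(object@traces))
    return("'info' must have one row per trace")
  TRUE
})
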