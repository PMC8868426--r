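#' @include AllClasses.R
NULL

#' @describeIn FattyAcylSpecies-class species label accessor
#'   ("FA C:db\[-OOH|-OOMxP\]").
#' @param object,x an object of the documented class.
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' @rdname monoisotopicMass
#' @export
setGeneric("monoisotopicMass",
           function(x) standardGeneric("monoisotopicMass"))

#' @rdname formulaOf
#' @export
setGeneric("formulaOf", function(x) standardGeneric("formulaOf"))

#' Carbon / double-bond / state accessors
#'
#' Read-only accessors for [FattyAcylSpecies-class] slots.
#'
#' @param x a `FattyAcylSpecies`.
#' @return integer count (`carbons()`, `doubleBonds()`) or character
#'   state (`acylState()`).
#' @examples
#' sp <- parseSpecies("FA 18:2-OOMxP")
#' carbons(sp); doubleBonds(sp); acylState(sp)
#' @export
setGeneric("carbons", function(x) standardGeneric("carbons"))

#' @rdname carbons
#' @export
setGeneric("doubleBonds", function(x) standardGeneric("doubleBonds"))

#' @rdname carbons
#' @export
setGeneric("acylState", function(x) standardGeneric("acylState"))

#' Ground-truth ledger of a simulated sample set
#'
#' Returns the hidden generative ledger attached to a [SampleSet-class]
#' (true amplitudes, expected areas, matrix multipliers). For test and
#' audit use only: estimators must not consume it.
#'
#' @param x a `SampleSet`.
#' @return a data.frame, one row per simulated trace.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Accessors for peak results
#'
#' @param x a [PeakResult-class].
#' @return numeric scalar (`peakArea`, `peakHeight`, `apexTime`,
#'   `noiseSd`, `snr`), logical (`isDetected`) or character vector
#'   (`qcFlags`).
#' @name peak-accessors
#' @export
setGeneric("peakArea", function(x) standardGeneric("peakArea"))

#' @rdname peak-accessors
#' @export
setGeneric("peakHeight", function(x) standardGeneric("peakHeight"))

#' @rdname peak-accessors
#' @export
setGeneric("apexTime", function(x) standardGeneric("apexTime"))

#' @rdname peak-accessors
#' @export
setGeneric("snr", function(x) standardGeneric("snr"))

#' @rdname peak-accessors
#' @export
setGeneric("noiseSd", function(x) standardGeneric("noiseSd"))

#' @rdname peak-accessors
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' @rdname peak-accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname internalStandard
#' @export
setGeneric("internalStandard",
           function(x) standardGeneric("internalStandard"))

#' @rdname retentionTimes
#' @export
setGeneric("retentionTimes",
           function(x) standardGeneric("retentionTimes"))
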