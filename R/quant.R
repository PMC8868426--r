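#' @include peaks.R
NULL

## per-level median replicate S/N -> grid-snapped LOD/LOQ (no
## interpolation; sentinel Inf when no level reaches the threshold)
.lodloqFromTable <- function(peakTable, lodSnr = 3, loqSnr = 10) {
  agg <- stats::aggregate(snr ~ level, data = peakTable, FUN = stats::median)
  agg <- agg[order(agg$level), ]
  lodLevels <- agg$level[agg$snr >= lodSnr]
  loqLevels <- agg$level[agg$snr >= loqSnr]
  list(lod = if (length(lodLevels)) min(lodLevels) else Inf,
       loq = if (length(loqLevels)) min(loqLevels) else Inf)
}

.responsesOf <- function(peakTable, species, responseMode) {
  sub <- peakTable[peakTable$species == species, , drop = FALSE]
  if (responseMode == "absolute_area") {
    sub$response <- sub$area
    return(sub)
  }
  isRows <- peakTable[peakTable$is_internal_standard, , drop = FALSE]
  isArea <- stats::setNames(isRows$area, isRows$sample_id)
  a <- isArea[sub$sample_id]
  if (anyNA(a) || any(a <= 0))
    stop("internal-standard area missing or zero; cannot form area ratios")
  sub$response <- sub$area / a
  sub
}

#' Determine LOD and LOQ from a calibration series
#'
#' The limit of detection (LOD) is the lowest prepared level whose
#' median replicate S/N is >= 3; the limit of quantification (LOQ) the
#' lowest with median S/N >= 10. Values snap to the prepared grid (no
#' interpolation); when no level reaches a threshold, `Inf` is
#' returned as an above-top-level sentinel.
#'
#' @param set a calibration [SampleSet-class] (or a peak table from
#'   [integrateSampleSet()]).
#' @param species analyte species label.
#' @param lodSnr,loqSnr S/N thresholds (defaults 3 and 10).
#' @param ... passed to [integrateSampleSet()] when `set` is a
#'   `SampleSet`.
#' @return list with numeric elements `lod` and `loq` (pmol/uL).
#' @export
determineLodLoq <- function(set, species, lodSnr = 3, loqSnr = 10,
                            ...) {
  peakTable <- if (is(set, "SampleSet"))
    integrateSampleSet(set, ...) else set
  sub <- peakTable[peakTable$species == species &
                     !peakTable$is_internal_standard, , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no calibration rows for species '%s'", species))
  .lodloqFromTable(sub, lodSnr, loqSnr)
}

#' Fit a calibration model
#'
#' Ordinary least squares of response versus concentration over the
#' prepared levels at or above the LOQ (sub-LOQ levels are excluded
#' from the fit but drive the LOD/LOQ determination). The response is
#' the analyte/internal-standard peak-area ratio by default, or the
#' absolute analyte area. At least 4 usable levels are required.
#'
#' @param set a calibration [SampleSet-class].
#' @param species analyte species label.
#' @param responseMode `"area_ratio_to_IS"` (default) or
#'   `"absolute_area"`.
#' @param rtMap,rtHalfWidth,minSnr,smoothWindow passed to
#'   [integrateSampleSet()].
#' @param lodSnr,loqSnr S/N thresholds for LOD/LOQ.
#' @return a [CalibrationModel-class].
#' @examples
#' sc <- SimScenario(seed = 3, species = "FA 18:2-OOMxP",
#'                   replicateCv = 0)
#' cal <- simulateCalibrationSeries(sc)
#' fitCalibration(cal, "FA 18:2-OOMxP")
#' @export
fitCalibration <- function(set, species,
                           responseMode = c("area_ratio_to_IS",
                                            "absolute_area"),
                           rtMap = NULL, rtHalfWidth = 0.3,
                           minSnr = 3, smoothWindow = 5L,
                           lodSnr = 3, loqSnr = 10) {
  responseMode <- match.arg(responseMode)
  peakTable <- integrateSampleSet(set, rtMap = rtMap,
                                  rtHalfWidth = rtHalfWidth,
                                  minSnr = minSnr,
                                  smoothWindow = smoothWindow)
  sub <- .responsesOf(peakTable, species, responseMode)
  sub <- sub[!sub$is_internal_standard, , drop = FALSE]
  ll <- .lodloqFromTable(sub, lodSnr, loqSnr)
  usable <- sub[sub$detected & !is.na(sub$level) &
                  sub$level >= ll$loq, , drop = FALSE]
  nLevels <- length(unique(usable$level))
  if (nLevels < 4L)
    stop(sprintf(
      "insufficient data: %d usable level(s) at/above LOQ, need >= 4",
      nLevels))
  fit <- stats::lm(response ~ level, data = usable)
  if (unname(stats::coef(fit)[2]) <= 0)
    stop("calibration rejected: no positive response-concentration relationship")
  new("CalibrationModel",
      species = species,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = summary(fit)$r.squared,
      linearRange = range(usable$level),
      lod = ll$lod, loq = ll$loq,
      responseMode = responseMode,
      nLevels = as.integer(nLevels))
}

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel %s: y = %.4gx %s %.4g, R^2 = %.3f, range %g-%g, LOD %g, LOQ %g pmol/uL (%s)\n",
    object@species, object@slope,
    if (object@intercept < 0) "-" else "+", abs(object@intercept),
    object@rSquared, object@linearRange[1], object@linearRange[2],
    object@lod, object@loq, object@responseMode))
})

#' Calibration summary table
#'
#' Tabulates a list of [CalibrationModel-class] objects in the layout
#' of a method-validation linearity table: linearity equation, R^2,
#' fitted range, LOD and LOQ.
#'
#' @param models list of `CalibrationModel` objects.
#' @return a data.frame with one row per model.
#' @export
calibrationTable <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(
      species = m@species,
      linearity = sprintf("%.4gx %s %.4g", m@slope,
                          if (m@intercept < 0) "-" else "+",
                          abs(m@intercept)),
      r_squared = round(m@rSquared, 3),
      range = sprintf("%g-%g", m@linearRange[1], m@linearRange[2]),
      lod = m@lod, loq = m@loq, row.names = NULL)
  }))
}

#' Extraction recovery
#'
#' `100 * area(spiked sample) / area(spiked extract)`: the fraction of
#' analyte surviving extraction, in percent. Replicate vectors are
#' paired element-wise; the replicate mean and SD are reported.
#'
#' @param spikedSampleArea,spikedExtractArea numeric vectors of peak
#'   areas (equal length or scalars); extract areas must be > 0.
#' @return list with `recovery_pct` (mean), `sd` and `values`.
#' @examples
#' computeRecovery(70, 100)
#' @export
computeRecovery <- function(spikedSampleArea, spikedExtractArea) {
  if (any(spikedExtractArea <= 0))
    stop("spiked-extract areas must be > 0")
  values <- 100 * spikedSampleArea / spikedExtractArea
  list(recovery_pct = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       values = values)
}

#' Matrix effect
#'
#' `100 * area(spiked extract) / area(neat standard)`: values below
#' 100% indicate ion suppression by the matrix, above 100% ion
#' enhancement.
#'
#' @param spikedExtractArea,neatStandardArea numeric vectors (equal
#'   length or scalars); neat areas must be > 0.
#' @return list with `matrix_effect_pct` (mean), `sd`, `values` and a
#'   `label` (`"ion suppression"`, `"ion enhancement"` or `"none"`).
#' @examples
#' computeMatrixEffect(91, 100)
#' @export
computeMatrixEffect <- function(spikedExtractArea, neatStandardArea) {
  if (any(neatStandardArea <= 0))
    stop("neat-standard areas must be > 0")
  values <- 100 * spikedExtractArea / neatStandardArea
  m <- mean(values)
  list(matrix_effect_pct = m,
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       values = values,
       label = if (m < 100) "ion suppression"
               else if (m > 100) "ion enhancement" else "none")
}

#' Coefficient of variation
#'
#' `100 * sd / mean`. `"standard"` pools all values; `"intraday"`
#' averages the within-day CVs; `"interday"` is the CV of the daily
#' means. Every group needs at least 3 replicates (interday: at least
#' 3 days).
#'
#' @param values numeric replicate measurements.
#' @param type `"standard"`, `"intraday"` or `"interday"`.
#' @param day day labels (required for intraday/interday).
#' @return numeric CV in percent.
#' @examples
#' computeCV(c(98, 100, 102))
#' @export
computeCV <- function(values, type = c("standard", "intraday",
                                       "interday"), day = NULL) {
  type <- match.arg(type)
  cv1 <- function(x) {
    if (length(x) < 3L)
      stop("CV requires >= 3 replicates per group")
    m <- mean(x)
    if (m == 0) stop("CV is undefined for zero-mean replicates")
    100 * stats::sd(x) / m
  }
  if (type == "standard") return(cv1(values))
  if (is.null(day) || length(day) != length(values))
    stop(sprintf("'%s' CV requires a day label per value", type))
  groups <- split(values, day)
  if (type == "intraday") return(mean(vapply(groups, cv1, numeric(1))))
  if (length(groups) < 3L)
    stop("inter-day CV requires >= 3 days")
  dailyMeans <- vapply(groups, mean, numeric(1))
  cv1(dailyMeans)
}

#' Summarize a validation experiment
#'
#' Computes the recovery, matrix effect and standard CV per analyte
#' from a [simulateValidationSet()]-style sample set (roles
#' `neat_standard`, `spiked_extract`, `spiked_sample`), and, when a
#' replicate set from [simulateReplicates()] is given, intra- and
#' inter-day CVs of the analyte/IS area ratio.
#'
#' @param valSet a validation [SampleSet-class].
#' @param repSet optional replicate [SampleSet-class] with `info$day`.
#' @param ... passed to [integrateSampleSet()].
#' @return a data.frame with one row per analyte: `recovery_pct`,
#'   `recovery_sd`, `matrix_effect_pct`, `cv_standard_pct` and (when
#'   `repSet` is given) `cv_intraday_pct`, `cv_interday_pct`, all CVs
#'   to 1 decimal.
#' @export
summarizeValidation <- function(valSet, repSet = NULL, ...) {
  pt <- integrateSampleSet(valSet, ...)
  analytes <- unique(pt$species[!pt$is_internal_standard])
  rows <- lapply(analytes, function(sp) {
    sub <- pt[pt$species == sp, , drop = FALSE]
    sub <- sub[order(sub$replicate), ]
    neat <- sub$area[sub$role == "neat_standard"]
    extract <- sub$area[sub$role == "spiked_extract"]
    sample <- sub$area[sub$role == "spiked_sample"]
    rec <- computeRecovery(sample, extract)
    me <- computeMatrixEffect(extract, neat)
    data.frame(species = sp,
               recovery_pct = round(rec$recovery_pct, 1),
               recovery_sd = round(rec$sd, 1),
               matrix_effect_pct = round(me$matrix_effect_pct, 1),
               cv_standard_pct = round(computeCV(neat), 1),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(repSet)) {
    rt <- integrateSampleSet(repSet, ...)
    isRows <- rt[rt$is_internal_standard, ]
    isArea <- stats::setNames(isRows$area, isRows$sample_id)
    cvs <- lapply(out$species, function(sp) {
      sub <- rt[rt$species == sp, , drop = FALSE]
      ratio <- sub$area / isArea[sub$sample_id]
      data.frame(
        cv_intraday_pct = round(computeCV(ratio, "intraday",
                                          day = sub$day), 1),
        cv_interday_pct = round(computeCV(ratio, "interday",
                                          day = sub$day), 1))
    })
    out <- cbind(out, do.call(rbind, cvs))
  }
  out
}

#' Quantify one sample against calibration models
#'
#' Internal-standard-normalized quantitation: each analyte's response
#' (peak-area ratio to the internal standard, or absolute area) is
#' inverted through its calibration model,
#' `concentration = (response - intercept) / slope`, in pmol/uL of the
#' final extract. The internal-standard peak must be detected with S/N
#' >= `minSnrIS`; otherwise the sample fails QC and no concentrations
#' are emitted. Results are graded: `ND` (not detected or below LOD),
#' `<LOQ`, `at_LOQ`, `extrapolated` (outside the fitted range) or
#' `ok`. An optional dilution chain back-calculates to source-volume
#' units (e.g. 50 uL serum brought to a 100 uL final extract).
#'
#' @param traces list of [ChromatogramTrace-class] for one sample, or a
#'   [SampleSet-class] together with `sampleId`.
#' @param models named list of [CalibrationModel-class] (names =
#'   species labels).
#' @param rtMap named numeric of expected retention times (minutes).
#' @param isLabel internal-standard species label.
#' @param sampleId sample to quantify when `traces` is a `SampleSet`.
#' @param minSnrIS IS acceptance threshold (default 10).
#' @param minSnr analyte detection threshold (default 3).
#' @param rtHalfWidth,smoothWindow peak-integration settings.
#' @param sourceVolume,finalVolume optional dilution chain (uL); when
#'   both are given, concentrations are rescaled by
#'   `finalVolume / sourceVolume` to pmol/uL of source material.
#' @return a data.frame with columns `sample`, `species`, `area`,
#'   `is_area`, `response`, `concentration`, `units`, `flags`. On IS
#'   failure the concentrations are all `NA` with flag
#'   `sample_QC_failed_IS` and attribute `qcFailed = TRUE`.
#' @export
quantifySample <- function(traces, models, rtMap,
                           isLabel = "FA 19:1-OOMxP",
                           sampleId = NULL, minSnrIS = 10, minSnr = 3,
                           rtHalfWidth = 0.3, smoothWindow = 5L,
                           sourceVolume = NULL, finalVolume = NULL) {
  if (is(traces, "SampleSet")) {
    if (is.null(sampleId)) {
      sids <- sampleIds(traces)
      if (length(sids) != 1L)
        stop("give 'sampleId' to pick a sample from the set")
      sampleId <- sids
    }
    info <- sampleInfo(traces)
    sel <- info$sample_id == sampleId
    traces <- traces@traces[sel]
  }
  traces <- .asTraceList(traces)
  bySpecies <- stats::setNames(traces,
                               vapply(traces, slot, character(1),
                                      "species"))
  sid <- if (!is.null(sampleId)) sampleId else traces[[1]]@sampleId

  integrateOne <- function(sp) {
    tr <- bySpecies[[sp]]
    if (is.null(tr)) return(NULL)
    rt <- rtMap[[sp]]
    if (is.null(rt)) stop(sprintf("no expected RT for '%s'", sp))
    win <- c(max(min(tr@times), rt - rtHalfWidth),
             min(max(tr@times), rt + rtHalfWidth))
    findPeak(tr, win, minSnr = minSnr, smoothWindow = smoothWindow)
  }

  scale <- 1
  units <- "pmol/uL_extract"
  if (!is.null(sourceVolume) && !is.null(finalVolume)) {
    scale <- finalVolume / sourceVolume
    units <- "pmol/uL_source"
  }

  isPeak <- integrateOne(isLabel)
  emptyRow <- function(sp, isArea, flag) {
    data.frame(sample = sid, species = sp, area = NA_real_,
               is_area = isArea, response = NA_real_,
               concentration = NA_real_, units = units, flags = flag)
  }
  if (is.null(isPeak) || !isPeak@detected || isPeak@snr < minSnrIS) {
    out <- do.call(rbind, lapply(names(models), emptyRow,
                                 isArea = NA_real_,
                                 flag = "sample_QC_failed_IS"))
    attr(out, "qcFailed") <- TRUE
    return(out)
  }
  isArea <- isPeak@area

  rows <- lapply(names(models), function(sp) {
    m <- models[[sp]]
    pk <- integrateOne(sp)
    if (is.null(pk)) return(emptyRow(sp, isArea, "no_trace"))
    response <- if (m@responseMode == "area_ratio_to_IS")
      pk@area / isArea else pk@area
    conc <- (response - m@intercept) / m@slope
    flags <- character()
    eps <- 1e-9 * max(1, m@loq)
    if (!pk@detected || (is.finite(m@lod) && conc < m@lod - eps)) {
      flags <- "ND"
      conc <- if (pk@detected) conc else NA_real_
    } else {
      if (abs(conc - m@loq) <= eps) flags <- c(flags, "at_LOQ")
      else if (conc < m@loq) flags <- c(flags, "<LOQ")
      if (conc < m@linearRange[1] - eps ||
          conc > m@linearRange[2] + eps)
        flags <- c(flags, "extrapolated")
      if (!length(flags)) flags <- "ok"
    }
    data.frame(sample = sid, species = sp, area = pk@area,
               is_area = isArea, response = response,
               concentration = conc * scale, units = units,
               flags = paste(flags, collapse = ","))
  })
  out <- do.call(rbind, rows)
  attr(out, "qcFailed") <- FALSE
  out
}

#' Write a quantitation or validation report
#'
#' @param df a report data.frame (e.g. from [quantifySample()] or
#'   [summarizeValidation()]).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param header optional character vector of `#` comment lines (TSV
#'   only; stored under `"_meta"` for JSON).
#' @return invisibly, the path.
#' @export
writeQuantReport <- function(df, path, format = c("tsv", "json"),
                             header = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- if (length(header))
      list(`_meta` = header, results = df) else list(results = df)
    jsonlite::write_json(payload, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
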