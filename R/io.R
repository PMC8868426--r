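#' @include simulate.R
NULL

## ---- internal CSV trace format ---------------------------------------

.asTraceList <- function(traces) {
  if (is(traces, "SampleSet")) return(traces@traces)
  if (is(traces, "ChromatogramTrace")) return(list(traces))
  stopifnot(is.list(traces),
            all(vapply(traces, is, logical(1), "ChromatogramTrace")))
  traces
}

#' Write traces to the internal CSV format
#'
#' Long format with columns `sample_id`, `species`, `time_min`,
#' `intensity`. Numbers are written with 17 significant digits so that
#' the round trip through [readTracesCSV()] reproduces the arrays
#' bit-for-bit. Optional `#` comment lines may precede the header.
#'
#' @param traces a [SampleSet-class], a [ChromatogramTrace-class] or a
#'   list of traces.
#' @param path output file path.
#' @param header optional character vector of comment lines (written
#'   `#`-prefixed).
#' @return invisibly, the path.
#' @export
writeTracesCSV <- function(traces, path, header = NULL) {
  traces <- .asTraceList(traces)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("sample_id,species,time_min,intensity", con)
  for (tr in traces) {
    writeLines(sprintf("%s,%s,%.17g,%.17g", tr@sampleId, tr@species,
                       tr@times, tr@intensities), con)
  }
  invisible(path)
}

#' Read traces from the internal CSV format
#'
#' @param path CSV file written by [writeTracesCSV()] (comment lines
#'   starting with `#` are skipped).
#' @return a named list of [ChromatogramTrace-class] objects, one per
#'   (sample, species) pair, in file order.
#' @export
readTracesCSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("trace file '%s' not found", path))
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("character", "character",
                                       "numeric", "numeric"))
  required <- c("sample_id", "species", "time_min", "intensity")
  if (!all(required %in% names(df)))
    stop("trace CSV must have columns: ",
         paste(required, collapse = ", "))
  keys <- unique(paste(df$sample_id, df$species, sep = "||"))
  out <- lapply(keys, function(k) {
    parts <- strsplit(k, "||", fixed = TRUE)[[1]]
    sel <- df$sample_id == parts[1] & df$species == parts[2]
    new("ChromatogramTrace", sampleId = parts[1], species = parts[2],
        times = df$time_min[sel], intensities = df$intensity[sel])
  })
  names(out) <- keys
  out
}

## ---- mzML -------------------------------------------------------------

.b64 <- function(x) {
  raw <- writeBin(as.double(x), raw(), size = 8, endian = "little")
  gsub("\n", "", jsonlite::base64_enc(raw))
}

.addCv <- function(node, accession, name, value = "", unit = NULL) {
  args <- list(node, "cvParam", cvRef = "MS", accession = accession,
               name = name, value = value)
  if (!is.null(unit))
    args <- c(args, list(unitCvRef = unit[1], unitAccession = unit[2],
                         unitName = unit[3]))
  do.call(xml2::xml_add_child, args)
}

#' Write SRM chromatograms to mzML
#'
#' Serializes traces as an mzML 1.1.0 chromatogram list (64-bit float,
#' no compression; time axis in minutes). Each chromatogram carries the
#' selected-reaction-monitoring CV term and precursor/product isolation
#' window target m/z taken from the transition registry, so standard
#' readers (e.g. Bioconductor's mzR) recover both the arrays and the
#' Q1/Q3 annotations.
#'
#' @param traces a [SampleSet-class], single trace, or list of traces.
#' @param path output file path.
#' @param registry a [TransitionRegistry-class] supplying Q1/Q3 m/z per
#'   species (default [buildRegistry()]).
#' @return invisibly, the path.
#' @seealso [readChromatogramsMzML()], [extractTrace()]
#' @export
writeChromatogramsMzML <- function(traces, path,
                                   registry = buildRegistry()) {
  traces <- .asTraceList(traces)
  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1.0")
  cvl <- xml2::xml_add_child(doc, "cvList", count = "2")
  xml2::xml_add_child(cvl, "cv", id = "MS", fullName = "PSI-MS",
    URI = "https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo")
  xml2::xml_add_child(cvl, "cv", id = "UO", fullName = "Unit Ontology",
    URI = "http://ontologies.berkeleybop.org/uo.obo")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  .addCv(fc, "MS:1001473", "selected reaction monitoring chromatogram")
  sl <- xml2::xml_add_child(doc, "softwareList", count = "1")
  sw <- xml2::xml_add_child(sl, "software", id = "faoohquant",
    version = as.character(utils::packageVersion("faoohquant")))
  .addCv(sw, "MS:1000799", "custom unreleased software tool",
         "faoohquant")
  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList",
                             count = "1")
  ic <- xml2::xml_add_child(icl, "instrumentConfiguration", id = "IC1")
  .addCv(ic, "MS:1000031", "instrument model")
  dpl <- xml2::xml_add_child(doc, "dataProcessingList", count = "1")
  dp <- xml2::xml_add_child(dpl, "dataProcessing", id = "DP1")
  pm <- xml2::xml_add_child(dp, "processingMethod", order = "1",
                            softwareRef = "faoohquant")
  .addCv(pm, "MS:1000544", "Conversion to mzML")
  run <- xml2::xml_add_child(doc, "run", id = "R1",
                             defaultInstrumentConfigurationRef = "IC1")
  chl <- xml2::xml_add_child(run, "chromatogramList",
                             count = as.character(length(traces)),
                             defaultDataProcessingRef = "DP1")
  mzUnit <- c("MS", "MS:1000040", "m/z")
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    trans <- registry[[tr@species]]
    id <- sprintf("SRM SIC Q1=%.1f Q3=%.1f sample=%s species=%s",
                  trans@parentMz, trans@productMz, tr@sampleId,
                  tr@species)
    ch <- xml2::xml_add_child(chl, "chromatogram",
      index = as.character(i - 1L), id = id,
      defaultArrayLength = as.character(length(tr@times)))
    .addCv(ch, "MS:1001473", "selected reaction monitoring chromatogram")
    prec <- xml2::xml_add_child(ch, "precursor")
    iw <- xml2::xml_add_child(prec, "isolationWindow")
    .addCv(iw, "MS:1000827", "isolation window target m/z",
           sprintf("%.6g", trans@parentMz), mzUnit)
    act <- xml2::xml_add_child(prec, "activation")
    .addCv(act, "MS:1000133", "collision-induced dissociation")
    prod <- xml2::xml_add_child(ch, "product")
    iw2 <- xml2::xml_add_child(prod, "isolationWindow")
    .addCv(iw2, "MS:1000827", "isolation window target m/z",
           sprintf("%.6g", trans@productMz), mzUnit)
    bal <- xml2::xml_add_child(ch, "binaryDataArrayList", count = "2")
    encT <- .b64(tr@times)
    b1 <- xml2::xml_add_child(bal, "binaryDataArray",
                              encodedLength = nchar(encT))
    .addCv(b1, "MS:1000523", "64-bit float")
    .addCv(b1, "MS:1000576", "no compression")
    .addCv(b1, "MS:1000595", "time array",
           unit = c("UO", "UO:0000031", "minute"))
    xml2::xml_add_child(b1, "binary", encT)
    encI <- .b64(tr@intensities)
    b2 <- xml2::xml_add_child(bal, "binaryDataArray",
                              encodedLength = nchar(encI))
    .addCv(b2, "MS:1000523", "64-bit float")
    .addCv(b2, "MS:1000576", "no compression")
    .addCv(b2, "MS:1000515", "intensity array",
           unit = c("MS", "MS:1000131", "number of detector counts"))
    xml2::xml_add_child(b2, "binary", encI)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.requireMzR <- function() {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
}

## parse "key=value" tokens out of a chromatogram id written by
## writeChromatogramsMzML; returns NA when absent. The species field is
## written last because its value contains spaces.
.idField <- function(id, key) {
  if (key == "species") {
    if (!grepl("species=", id, fixed = TRUE)) return(NA_character_)
    return(sub(".*species=", "", id))
  }
  m <- regmatches(id, regexpr(paste0(key, "=[^ ]+"), id))
  if (!length(m)) return(NA_character_)
  sub(paste0("^", key, "="), "", m)
}

#' Read SRM chromatograms from mzML
#'
#' Reads all chromatograms of an mzML file through Bioconductor's mzR
#' and returns them as [ChromatogramTrace-class] objects. Sample and
#' species annotations are recovered from the chromatogram ids when the
#' file was written by [writeChromatogramsMzML()]; otherwise the id is
#' used as species label.
#'
#' @param path mzML file path.
#' @return a list of [ChromatogramTrace-class] objects.
#' @export
readChromatogramsMzML <- function(path) {
  .requireMzR()
  if (!file.exists(path)) stop(sprintf("mzML file '%s' not found", path))
  f <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(f))
  hdr <- mzR::chromatogramHeader(f)
  out <- lapply(seq_len(nrow(hdr)), function(i) {
    cc <- mzR::chromatogram(f, i)
    id <- hdr$chromatogramId[i]
    sp <- .idField(id, "species")
    sid <- .idField(id, "sample")
    new("ChromatogramTrace",
        sampleId = if (is.na(sid)) "unknown" else sid,
        species = if (is.na(sp)) id else sp,
        times = cc[[1]], intensities = pmax(cc[[2]], 0))
  })
  names(out) <- vapply(out, function(tr)
    .traceKey(tr@sampleId, tr@species), character(1))
  out
}

#' Extract the trace matching a transition
#'
#' Finds the chromatogram whose precursor and product annotations both
#' match an [SRMTransition-class] within `mzTolerance`. For mzML
#' sources, matching uses the isolation-window target m/z read through
#' mzR, an exact m/z match being preferred over a nearest match; an
#' ambiguous match (several channels within tolerance, none exact)
#' raises an error asking for a tighter tolerance, and no match raises
#' a not-found error listing the available channels. For internal-CSV
#' sources and [SampleSet-class] objects, traces are keyed by species
#' label and matched directly.
#'
#' @param source an mzML path, an internal-CSV path, a list of traces,
#'   or a [SampleSet-class].
#' @param transition an [SRMTransition-class] (or species label for
#'   label-keyed sources).
#' @param mzTolerance numeric, Da (> 0; default 0.2).
#' @param sampleId sample id, required when the source holds several
#'   samples.
#' @return a [ChromatogramTrace-class].
#' @export
extractTrace <- function(source, transition, mzTolerance = 0.2,
                         sampleId = NULL) {
  if (!is.numeric(mzTolerance) || mzTolerance <= 0)
    stop("'mzTolerance' must be > 0")
  isMzml <- is.character(source) && length(source) == 1L &&
    grepl("\\.mzml$", source, ignore.case = TRUE)
  if (isMzml) {
    if (!is(transition, "SRMTransition"))
      stop("mzML extraction requires an SRMTransition")
    return(.extractTraceMzml(source, transition, mzTolerance, sampleId))
  }
  label <- if (is(transition, "SRMTransition"))
    speciesLabel(transition@species) else as.character(transition)
  traces <- if (is.character(source)) readTracesCSV(source)
            else .asTraceList(source)
  hits <- Filter(function(tr) tr@species == label, traces)
  if (!length(hits))
    stop(sprintf("no trace for '%s' (available: %s)", label,
                 paste(unique(vapply(traces, slot, character(1),
                                     "species")), collapse = ", ")))
  if (!is.null(sampleId)) {
    hits <- Filter(function(tr) tr@sampleId == sampleId, hits)
    if (!length(hits))
      stop(sprintf("no trace for '%s' in sample '%s'", label, sampleId))
  }
  if (length(hits) > 1L)
    stop(sprintf(
      "trace for '%s' is ambiguous across samples (%s); give 'sampleId'",
      label, paste(vapply(hits, slot, character(1), "sampleId"),
                   collapse = ", ")))
  hits[[1]]
}

.extractTraceMzml <- function(path, transition, tol, sampleId) {
  .requireMzR()
  f <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(f))
  hdr <- mzR::chromatogramHeader(f)
  if (!is.null(sampleId)) {
    sids <- vapply(hdr$chromatogramId, .idField, character(1), "sample")
    keep <- !is.na(sids) & sids == sampleId
    hdr <- hdr[keep, , drop = FALSE]
  }
  if (!nrow(hdr))
    stop("mzML file contains no matching chromatograms")
  dParent <- abs(hdr$precursorIsolationWindowTargetMZ -
                   transition@parentMz)
  dProduct <- abs(hdr$productIsolationWindowTargetMZ -
                    transition@productMz)
  within <- !is.na(dParent) & !is.na(dProduct) &
    dParent <= tol & dProduct <= tol
  if (!any(within)) {
    avail <- sprintf("%.1f/%.1f", hdr$precursorIsolationWindowTargetMZ,
                     hdr$productIsolationWindowTargetMZ)
    stop(sprintf(
      "no chromatogram matches %.1f/%.1f within %.3g Da (available: %s)",
      transition@parentMz, transition@productMz, tol,
      paste(unique(avail), collapse = ", ")))
  }
  idx <- which(within)
  if (length(idx) > 1L) {
    exact <- idx[dParent[idx] < 1e-9 & dProduct[idx] < 1e-9]
    if (length(exact) == 1L) idx <- exact
    else stop(sprintf(
      "ambiguous match: %d chromatograms within %.3g Da of %.1f/%.1f; use a tighter tolerance",
      length(idx), tol, transition@parentMz, transition@productMz))
  }
  cc <- mzR::chromatogram(f, hdr$chromatogramIndex[idx])
  id <- hdr$chromatogramId[idx]
  sp <- .idField(id, "species")
  sid <- .idField(id, "sample")
  new("ChromatogramTrace",
      sampleId = if (is.na(sid)) "unknown" else sid,
      species = if (is.na(sp)) speciesLabel(transition@species) else sp,
      times = cc[[1]], intensities = pmax(cc[[2]], 0))
}
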