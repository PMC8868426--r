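#' @include chem.R
NULL

## Empirical neutral losses fitted to the tuned assay table: the
## poly-unsaturated product is the nominal loss of the MxP unit
## (C4H8O, 72.0), the mono-unsaturated product an empirical 202.1 Da
## loss (mean of the observed 201.9/202.1/202.1 differences; its
## chemical identity is not established).
.LOSS_POLY <- 72.0
.LOSS_MONO <- 202.1

#' Construct an SRM transition
#'
#' @param species a [FattyAcylSpecies-class] (state `"OOMxP"`) or label.
#' @param parentMz,productMz numeric m/z at 1 decimal.
#' @param collisionEnergy,tubeLens numeric, volts.
#' @param polarity `"positive"` (default) or `"negative"`.
#' @param isInternalStandard logical flag.
#' @return an [SRMTransition-class].
#' @export
SRMTransition <- function(species, parentMz, productMz,
                          collisionEnergy, tubeLens,
                          polarity = "positive",
                          isInternalStandard = FALSE) {
  if (is.character(species)) species <- parseSpecies(species)
  new("SRMTransition", species = species,
      parentMz = as.numeric(parentMz),
      productMz = as.numeric(productMz),
      collisionEnergy = as.numeric(collisionEnergy),
      tubeLens = as.numeric(tubeLens),
      polarity = polarity,
      isInternalStandard = isInternalStandard)
}

setMethod("show", "SRMTransition", function(object) {
  cat(sprintf("SRMTransition: %s%s  %.1f -> %.1f  (CE %g V, tube lens %g V, %s)\n",
              speciesLabel(object@species),
              if (object@isInternalStandard) " (IS)" else "",
              object@parentMz, object@productMz,
              object@collisionEnergy, object@tubeLens, object@polarity))
})

#' Predict the SRM parent ion m/z
#'
#' Theoretical sodiated precursor m/z of a 2-MxP derivatized fatty acid
#' hydroperoxide: `[M+Na]+` of the neutral formula from [formulaOf()],
#' rounded half-away-from-zero to 1 decimal. Underivatized species are
#' not assayed in positive mode and raise an error.
#'
#' @param species a [FattyAcylSpecies-class] in state `"OOMxP"`, or a
#'   label parseable by [parseSpecies()].
#' @return numeric m/z at 1 decimal.
#' @examples
#' predictParentMz("FA 18:2-OOMxP") # 407.3
#' predictParentMz("FA 22:1-OOMxP") # 465.4
#' @export
predictParentMz <- function(species) {
  if (is.character(species)) species <- parseSpecies(species)
  if (species@state != "OOMxP")
    stop(sprintf(
      "parent m/z is defined for OOMxP derivatives only (got state '%s')",
      species@state))
  adductMz(monoisotopicMass(formulaOf(species)), "[M+Na]+", digits = 1)
}

#' Predict the SRM product ion m/z
#'
#' Applies the unsaturation-dependent neutral-loss rules to a parent
#' m/z: poly-unsaturated species (db >= 2) lose the nominal MxP unit
#' (72.0 Da, C4H8O); mono-unsaturated species lose an empirical
#' 202.1 Da. Saturated species carry no allylic -OOH and raise an
#' error.
#'
#' @param species a [FattyAcylSpecies-class] (state `"OOMxP"`) or label.
#' @param parentMz numeric parent m/z (predicted or registry value).
#' @return numeric product m/z at 1 decimal.
#' @examples
#' predictProductMz("FA 18:2-OOMxP", 407.3) # 335.3
#' predictProductMz("FA 22:1-OOMxP", 465.4) # 263.3
#' @export
predictProductMz <- function(species, parentMz) {
  if (is.character(species)) species <- parseSpecies(species)
  if (species@state != "OOMxP")
    stop("product m/z is defined for OOMxP derivatives only")
  if (species@doubleBonds == 0L)
    stop("saturated species carry no hydroperoxide product ion")
  loss <- if (species@doubleBonds >= 2L) .LOSS_POLY else .LOSS_MONO
  .roundHalfAway(parentMz - loss, 1)
}

#' Build the default transition registry
#'
#' Returns the packaged instrument-optimized SRM assay: 8 channels for
#' the 2-MxP derivatized hydroperoxides of FA 18:1, 18:2, 18:3, 20:4,
#' 20:5, 22:1, 22:6 and the internal standard FA 19:1, with tuned
#' parent/product m/z, collision energies and tube-lens voltages. The
#' printed tuned values are authoritative for acquisition and matching;
#' [predictParentMz()]/[predictProductMz()] serve as advisory QC (see
#' [validateAgainstRegistry()]).
#'
#' @return a [TransitionRegistry-class] of 8 transitions.
#' @examples
#' reg <- buildRegistry()
#' length(reg)
#' reg[["FA 19:1-OOMxP"]]
#' @export
buildRegistry <- function() {
  path <- system.file("extdata", "default_transitions.csv",
                      package = "faoohquant", mustWork = TRUE)
  importTransitionList(path)
}

#' Import a transition list from CSV
#'
#' Reads a vendor-style mass-list CSV with columns `species`,
#' `precursor_mz`, `product_mz`, `collision_energy`, `tube_lens`,
#' `polarity`, `is_internal_standard` (header mandatory; extra columns
#' ignored; comment lines starting with `#` allowed).
#'
#' @param path file path.
#' @return a [TransitionRegistry-class].
#' @seealso [exportTransitionList()]
#' @export
importTransitionList <- function(path) {
  if (!file.exists(path))
    stop(sprintf("transition list '%s' not found", path))
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  required <- c("species", "precursor_mz", "product_mz",
                "collision_energy", "tube_lens", "polarity",
                "is_internal_standard")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("transition list is missing column(s): ",
         paste(missing, collapse = ", "))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    SRMTransition(df$species[i], df$precursor_mz[i], df$product_mz[i],
                  df$collision_energy[i], df$tube_lens[i],
                  df$polarity[i], as.logical(df$is_internal_standard[i]))
  })
  new("TransitionRegistry", entries = entries)
}

#' Export a transition list to CSV
#'
#' Writes the registry in the same column schema read by
#' [importTransitionList()]; the round trip is field-for-field exact.
#'
#' @param registry a [TransitionRegistry-class].
#' @param path output file path.
#' @param header optional character vector of `#`-prefixed comment
#'   lines written before the column header.
#' @return invisibly, the path.
#' @export
exportTransitionList <- function(registry, path, header = NULL) {
  df <- as.data.frame(registry)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    rows <- apply(df, 1L, function(r) paste(trimws(r), collapse = ","))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @describeIn TransitionRegistry-class number of transitions.
#' @param x a `TransitionRegistry`.
#' @export
setMethod("length", "TransitionRegistry", function(x) length(x@entries))

#' @describeIn TransitionRegistry-class species labels, in table order.
#' @export
setMethod("names", "TransitionRegistry", function(x) {
  vapply(x@entries, function(e) speciesLabel(e@species), character(1))
})

#' @describeIn TransitionRegistry-class look up a transition by species
#'   label; unknown labels raise a not-found error.
#' @param i species label.
#' @param j,... unused.
#' @export
setMethod("[[", "TransitionRegistry", function(x, i, j, ...) {
  labs <- names(x)
  hit <- match(i, labs)
  if (is.na(hit))
    stop(sprintf("species '%s' not found in registry (available: %s)",
                 i, paste(labs, collapse = ", ")))
  x@entries[[hit]]
})

#' Internal standard of a registry
#'
#' @param x a [TransitionRegistry-class].
#' @return the flagged internal-standard [SRMTransition-class].
#' @export
setMethod("internalStandard", "TransitionRegistry", function(x) {
  isFlag <- vapply(x@entries, slot, logical(1), "isInternalStandard")
  x@entries[[which(isFlag)]]
})

#' @export
as.data.frame.TransitionRegistry <- function(x, ...) {
  data.frame(
    species = names(x),
    precursor_mz = vapply(x@entries, slot, numeric(1), "parentMz"),
    product_mz = vapply(x@entries, slot, numeric(1), "productMz"),
    collision_energy = vapply(x@entries, slot, numeric(1),
                              "collisionEnergy"),
    tube_lens = vapply(x@entries, slot, numeric(1), "tubeLens"),
    polarity = vapply(x@entries, slot, character(1), "polarity"),
    is_internal_standard = vapply(x@entries, slot, logical(1),
                                  "isInternalStandard"),
    row.names = NULL
  )
}

setMethod("show", "TransitionRegistry", function(object) {
  cat(sprintf("TransitionRegistry with %d transition%s\n",
              length(object), if (length(object) == 1) "" else "s"))
  print(as.data.frame(object))
})

#' Validate a registry against theoretical predictions
#'
#' Compares every registry parent/product m/z with the theoretical
#' prediction ([predictParentMz()]; [predictProductMz()] applied to the
#' registry parent) and reports absolute deviations in descending
#' order. The validation passes iff all deviations are within
#' `tolerance`. Tuned instrument values are expected to deviate from
#' theory by up to ~0.13 Da before rounding, hence the 0.2 Da default.
#'
#' @param registry a [TransitionRegistry-class].
#' @param tolerance numeric, Da (> 0; default 0.2).
#' @return an object of class `registryValidation`: a list with
#'   elements `pass` (logical), `tolerance`, and `deviations` (a
#'   data.frame with species, quantity, registry/predicted m/z and
#'   absolute deviation, sorted descending).
#' @examples
#' validateAgainstRegistry(buildRegistry())
#' @export
validateAgainstRegistry <- function(registry, tolerance = 0.2) {
  if (!length(registry@entries)) stop("registry is empty")
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("'tolerance' must be > 0")
  rows <- lapply(registry@entries, function(e) {
    sp <- e@species
    predParent <- predictParentMz(sp)
    predProduct <- predictProductMz(sp, e@parentMz)
    data.frame(
      species = rep(speciesLabel(sp), 2L),
      quantity = c("parent", "product"),
      registry_mz = c(e@parentMz, e@productMz),
      predicted_mz = c(predParent, predProduct),
      deviation = round(abs(c(predParent - e@parentMz,
                              predProduct - e@productMz)), 6)
    )
  })
  dev <- do.call(rbind, rows)
  dev <- dev[order(-dev$deviation, dev$species), ]
  rownames(dev) <- NULL
  structure(
    list(pass = all(dev$deviation <= tolerance),
         tolerance = tolerance,
         deviations = dev),
    class = "registryValidation"
  )
}

#' @export
print.registryValidation <- function(x, ...) {
  cat(sprintf("Registry validation: %s (tolerance %.3g Da)\n",
              if (x$pass) "PASS" else "FAIL", x$tolerance))
  offenders <- x$deviations[x$deviations$deviation > x$tolerance, ]
  if (nrow(offenders)) {
    cat("Offending channels:\n")
    print(offenders)
  } else {
    cat(sprintf("Max deviation: %.3g Da\n", max(x$deviations$deviation)))
  }
  invisible(x)
}
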