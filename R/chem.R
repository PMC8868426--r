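#' @include AllGenerics.R
NULL

## Pinned monoisotopic masses (Da). The 4-decimal exact-mass targets
## (313.2384 for [M-H]- of FA 18:1-OOH, 409.2924 for [M+Na]+ of its
## 2-MxP derivative) require the electron-mass correction.
.ELEMENT_MASSES <- c(
  C  = 12.000000,
  H  = 1.00782503,
  O  = 15.99491462,
  Na = 22.98976928
)
.ELECTRON_MASS <- 0.00054858

#' Pinned atomic monoisotopic masses
#'
#' The monoisotopic atomic masses (Da) used by all mass arithmetic in
#' the package, plus the electron mass applied in adduct corrections.
#'
#' @return named numeric vector with elements `C`, `H`, `O`, `Na` and
#'   `electron`.
#' @examples
#' atomicMasses()
#' @export
atomicMasses <- function() {
  c(.ELEMENT_MASSES, electron = .ELECTRON_MASS)
}

## Round half away from zero (base round() is round-half-even).
## A tiny relative nudge absorbs float representation error so that
## values printed as exact halves round away from zero.
.roundHalfAway <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Construct a fatty acyl species
#'
#' @param carbons integer acyl carbon count (>= 2).
#' @param doubleBonds integer double-bond count.
#' @param state `"FREE"`, `"OOH"` or `"OOMxP"`.
#' @return a [FattyAcylSpecies-class].
#' @examples
#' FattyAcylSpecies(18, 2, "OOMxP")
#' @export
FattyAcylSpecies <- function(carbons, doubleBonds, state = "FREE") {
  new("FattyAcylSpecies",
      carbons = as.integer(carbons),
      doubleBonds = as.integer(doubleBonds),
      state = as.character(state))
}

#' Parse a species label
#'
#' Parses the shorthand grammar `"FA <carbons>:<doubleBonds>[-OOH|-OOMxP]"`
#' used throughout the assay (e.g. `"FA 18:2-OOMxP"`, the internal
#' standard `"FA 19:1-OOH"`). Labels round-trip through
#' [speciesLabel()].
#'
#' @param label character scalar species label.
#' @return a [FattyAcylSpecies-class].
#' @examples
#' parseSpecies("FA 18:2-OOMxP")
#' parseSpecies("FA 19:1-OOH")
#' @export
parseSpecies <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("'label' must be a single character string")
  m <- regexec("^FA ([0-9]+):([0-9]+)(-OOH|-OOMxP)?$", label)
  parts <- regmatches(label, m)[[1]]
  if (!length(parts)) {
    ## name the offending token: first thing that breaks the grammar
    bad <- if (!grepl("^FA ", label)) strsplit(label, " ")[[1]][1]
           else sub("^FA ", "", label)
    stop(sprintf("malformed species label '%s': offending token '%s' %s",
                 label, bad,
                 "(expected \"FA <carbons>:<db>[-OOH|-OOMxP]\")"))
  }
  state <- switch(parts[4],
                  "-OOH" = "OOH",
                  "-OOMxP" = "OOMxP",
                  "FREE")
  FattyAcylSpecies(as.integer(parts[2]), as.integer(parts[3]), state)
}

#' @rdname speciesLabel
#' @export
setMethod("speciesLabel", "FattyAcylSpecies", function(x) {
  suffix <- switch(x@state, FREE = "", OOH = "-OOH", OOMxP = "-OOMxP")
  sprintf("FA %d:%d%s", x@carbons, x@doubleBonds, suffix)
})

#' @rdname carbons
#' @export
setMethod("carbons", "FattyAcylSpecies", function(x) x@carbons)

#' @rdname carbons
#' @export
setMethod("doubleBonds", "FattyAcylSpecies", function(x) x@doubleBonds)

#' @rdname carbons
#' @export
setMethod("acylState", "FattyAcylSpecies", function(x) x@state)

setMethod("show", "FattyAcylSpecies", function(object) {
  cat(sprintf("FattyAcylSpecies: %s (C%d, %d double bond%s, state %s)\n",
              speciesLabel(object), object@carbons, object@doubleBonds,
              if (object@doubleBonds == 1L) "" else "s", object@state))
})

#' Construct a molecular formula
#'
#' @param counts named numeric vector of element counts, e.g.
#'   `c(C = 18, H = 34, O = 4)`. Zero counts are dropped.
#' @return a [MolecularFormula-class].
#' @examples
#' MolecularFormula(c(C = 18, H = 34, O = 2))
#' @export
MolecularFormula <- function(counts = numeric()) {
  counts <- counts[counts != 0]
  new("MolecularFormula", counts = counts)
}

#' @export
setMethod("+", signature("MolecularFormula", "MolecularFormula"),
  function(e1, e2) {
    els <- union(names(e1@counts), names(e2@counts))
    cts <- vapply(els, function(el) {
      sum(e1@counts[el], e2@counts[el], na.rm = TRUE)
    }, numeric(1))
    MolecularFormula(cts)
  })

#' Element counts of a formula
#'
#' @param x a [MolecularFormula-class].
#' @return named numeric vector of counts.
#' @export
elementCounts <- function(x) {
  stopifnot(is(x, "MolecularFormula"))
  x@counts
}

#' Hill-notation formula string
#'
#' @param x a [MolecularFormula-class].
#' @return character scalar, e.g. `"C22H42O5"`.
#' @examples
#' formulaString(formulaOf(parseSpecies("FA 18:1-OOMxP")))
#' @export
formulaString <- function(x) {
  cts <- elementCounts(x)
  if (!length(cts)) return("")
  hill <- c(intersect(c("C", "H"), names(cts)),
            sort(setdiff(names(cts), c("C", "H"))))
  paste0(vapply(hill, function(el) {
    n <- cts[[el]]
    if (n == 1) el else sprintf("%s%d", el, n)
  }, character(1)), collapse = "")
}

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", formulaString(object), "\n")
})

#' Molecular formula of a fatty acyl species
#'
#' Builds the neutral-molecule formula along the derivatization ladder:
#' the free acid is `C_n H_(2n - 2 db) O2`; hydroperoxidation adds `O2`;
#' 2-MxP derivatization adds `C4H8O` (the enol ether adds across the
#' -OOH group to form the perketal). Adducts are applied separately by
#' [adductMz()].
#'
#' @param x a [FattyAcylSpecies-class].
#' @return a [MolecularFormula-class] for the neutral molecule.
#' @examples
#' formulaString(formulaOf(parseSpecies("FA 18:1")))       # C18H34O2
#' formulaString(formulaOf(parseSpecies("FA 18:1-OOH")))   # C18H34O4
#' formulaString(formulaOf(parseSpecies("FA 18:1-OOMxP"))) # C22H42O5
#' @export
setMethod("formulaOf", "FattyAcylSpecies", function(x) {
  n <- x@carbons
  db <- x@doubleBonds
  f <- MolecularFormula(c(C = n, H = 2 * n - 2 * db, O = 2))
  if (x@state %in% c("OOH", "OOMxP"))
    f <- f + MolecularFormula(c(O = 2))
  if (x@state == "OOMxP")
    f <- f + MolecularFormula(c(C = 4, H = 8, O = 1))
  f
})

#' Monoisotopic mass
#'
#' Sum of element counts times the pinned monoisotopic atomic masses
#' (see [atomicMasses()]). Supported elements: C, H, O, Na. The method
#' for [FattyAcylSpecies-class] is a shorthand for
#' `monoisotopicMass(formulaOf(x))`.
#'
#' @param x a [MolecularFormula-class] or [FattyAcylSpecies-class].
#' @return numeric, neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass(parseSpecies("FA 18:1-OOH")) # 314.24571
#' @export
setMethod("monoisotopicMass", "MolecularFormula", function(x) {
  cts <- elementCounts(x)
  if (!length(cts)) return(0)
  unknown <- setdiff(names(cts), names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  sum(cts * .ELEMENT_MASSES[names(cts)])
})

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "FattyAcylSpecies", function(x) {
  monoisotopicMass(formulaOf(x))
})

.ADDUCTS <- list(
  "[M-H]-"  = list(delta = -.ELEMENT_MASSES[["H"]] + .ELECTRON_MASS,
                   charge = -1L),
  "[M+H]+"  = list(delta = +.ELEMENT_MASSES[["H"]] - .ELECTRON_MASS,
                   charge = +1L),
  "[M+Na]+" = list(delta = +.ELEMENT_MASSES[["Na"]] - .ELECTRON_MASS,
                   charge = +1L)
)

## accept the unicode minus sign users paste from papers
.normalizeAdduct <- function(name) {
  gsub("−", "-", name)
}

#' Supported adducts
#'
#' @return data.frame of adduct names, signed mass deltas (Da, electron
#'   correction included) and charge signs.
#' @export
adductTable <- function() {
  data.frame(
    name = names(.ADDUCTS),
    delta_mass = vapply(.ADDUCTS, function(a) a$delta, numeric(1)),
    charge = vapply(.ADDUCTS, function(a) a$charge, integer(1)),
    row.names = NULL
  )
}

#' Adduct m/z
#'
#' m/z of a singly charged adduct of a neutral molecule:
#' `neutral_mass + delta_mass`, where the delta includes the electron
#' correction (e.g. \[M+Na\]+ adds the Na mass minus one electron).
#'
#' @param neutralMass numeric, neutral monoisotopic mass in Da (> 0).
#' @param adduct adduct name: `"[M-H]-"`, `"[M+H]+"` or `"[M+Na]+"`.
#' @param digits decimals for reporting: 4 (default, exact-mass
#'   context) or 1 (SRM context); `NULL` returns the unrounded value.
#'   Rounding is half-away-from-zero.
#' @return numeric m/z.
#' @examples
#' adductMz(monoisotopicMass(parseSpecies("FA 18:1-OOH")), "[M-H]-")
#' # 313.2384
#' adductMz(monoisotopicMass(parseSpecies("FA 18:1-OOMxP")), "[M+Na]+")
#' # 409.2924
#' @export
adductMz <- function(neutralMass, adduct = "[M+Na]+", digits = 4) {
  if (!is.numeric(neutralMass) || any(neutralMass <= 0))
    stop("'neutralMass' must be > 0")
  adduct <- .normalizeAdduct(adduct)
  if (!adduct %in% names(.ADDUCTS))
    stop(sprintf("unknown adduct '%s' (supported: %s)", adduct,
                 paste(names(.ADDUCTS), collapse = ", ")))
  mz <- neutralMass + .ADDUCTS[[adduct]]$delta
  if (is.null(digits)) mz else .roundHalfAway(mz, digits)
}

#' ppm mass error
#'
#' Relative deviation of an experimental from a theoretical m/z in
#' parts per million: `(experimental - theoretical) / theoretical * 1e6`.
#'
#' @param experimental,theoretical numeric m/z values; `theoretical`
#'   must be > 0.
#' @param digits decimals for reporting (default 2, rounded
#'   half-away-from-zero); `NULL` returns the unrounded value.
#' @return numeric ppm error.
#' @examples
#' ppmError(409.2917, 409.2924) # -1.71
#' @export
ppmError <- function(experimental, theoretical, digits = 2) {
  if (!is.numeric(theoretical) || any(theoretical <= 0))
    stop("'theoretical' must be > 0")
  ppm <- (experimental - theoretical) / theoretical * 1e6
  if (is.null(digits)) ppm else .roundHalfAway(ppm, digits)
}
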