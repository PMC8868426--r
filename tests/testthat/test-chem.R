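# Formula and exact-mass arithmetic for the FAOOH -> FAOOMxP ladder.

# Independent element-by-element oracle, kept separate from the
# package's mass table on purpose.
oracleMass <- function(nC, nH, nO, nNa = 0) {
  nC * 12 + nH * 1.00782503 + nO * 15.99491462 + nNa * 22.98976928
}
ELECTRON <- 0.00054858

test_that("species labels parse and round-trip through the grammar", {
  sp <- parseSpecies("FA 18:2-OOMxP")
  expect_equal(carbons(sp), 18L)
  expect_equal(doubleBonds(sp), 2L)
  expect_equal(acylState(sp), "OOMxP")

  is <- parseSpecies("FA 19:1-OOH")
  expect_equal(carbons(is), 19L)
  expect_equal(doubleBonds(is), 1L)
  expect_equal(acylState(is), "OOH")

  free <- parseSpecies("FA 18:1")
  expect_equal(acylState(free), "FREE")

  # round trip over a grid of valid species
  for (n in c(18L, 19L, 20L, 22L)) {
    for (db in 0:5) {
      for (suffix in c("", "-OOH", "-OOMxP")) {
        if (db > (n - 2) %/% 2) next
        if (suffix != "" && db < 1) next
        lab <- sprintf("FA %d:%d%s", n, db, suffix)
        expect_identical(speciesLabel(parseSpecies(lab)), lab)
      }
    }
  }
})

test_that("invalid species labels are rejected with useful errors", {
  # saturated acyl cannot carry an allylic hydroperoxide
  expect_error(parseSpecies("FA 18:0-OOH"), "double bond")
  expect_error(parseSpecies("FA 18:0-OOMxP"), "double bond")
  # malformed labels name the offending token
  expect_error(parseSpecies("PC 18:1"), "PC")
  expect_error(parseSpecies("FA 18.1"), "18\\.1")
  expect_error(parseSpecies("FA 18:2-OOX"), "malformed")
  # chemically impossible double-bond counts
  expect_error(parseSpecies("FA 18:9"), "maximum")
  expect_error(FattyAcylSpecies(1, 0), "carbons")
})

test_that("the derivatization ladder adds O2 then C4H8O", {
  for (n in c(18L, 20L, 22L)) {
    for (db in 1:4) {
      free <- elementCounts(formulaOf(FattyAcylSpecies(n, db, "FREE")))
      ooh <- elementCounts(formulaOf(FattyAcylSpecies(n, db, "OOH")))
      mxp <- elementCounts(formulaOf(FattyAcylSpecies(n, db, "OOMxP")))
      expect_equal(ooh[["O"]] - free[["O"]], 2)
      expect_equal(ooh[["C"]], free[["C"]])
      expect_equal(ooh[["H"]], free[["H"]])
      expect_equal(mxp[["C"]] - ooh[["C"]], 4)
      expect_equal(mxp[["H"]] - ooh[["H"]], 8)
      expect_equal(mxp[["O"]] - ooh[["O"]], 1)
    }
  }
  expect_identical(formulaString(formulaOf(parseSpecies("FA 18:1"))),
                   "C18H34O2")
  expect_identical(formulaString(formulaOf(parseSpecies("FA 18:1-OOH"))),
                   "C18H34O4")
  expect_identical(
    formulaString(formulaOf(parseSpecies("FA 18:1-OOMxP"))), "C22H42O5")
})

test_that("monoisotopic masses match an independent hand computation", {
  expect_equal(monoisotopicMass(parseSpecies("FA 18:1-OOH")),
               oracleMass(18, 34, 4), tolerance = 1e-9)
  expect_equal(monoisotopicMass(parseSpecies("FA 18:1-OOH")),
               314.24571, tolerance = 1e-5)
  expect_equal(monoisotopicMass(parseSpecies("FA 18:1-OOMxP")),
               oracleMass(22, 42, 5), tolerance = 1e-9)
  expect_equal(monoisotopicMass(parseSpecies("FA 18:1-OOMxP")),
               386.30322, tolerance = 1e-5)
  expect_equal(monoisotopicMass(MolecularFormula()), 0)
  expect_error(monoisotopicMass(MolecularFormula(c(C = 1, S = 1))), "S")
})

test_that("formula addition is element-wise, commutative, mass-additive", {
  a <- MolecularFormula(c(C = 18, H = 32, O = 2))
  b <- MolecularFormula(c(O = 2))
  expect_identical(elementCounts(a + b), elementCounts(b + a)[
    names(elementCounts(a + b))])
  set.seed(42)
  for (i in 1:20) {
    f1 <- MolecularFormula(c(C = sample(30, 1), H = sample(60, 1),
                             O = sample(8, 1)))
    f2 <- MolecularFormula(c(H = sample(10, 1), O = sample(4, 1),
                             Na = sample(2, 1)))
    expect_equal(monoisotopicMass(f1 + f2),
                 monoisotopicMass(f1) + monoisotopicMass(f2),
                 tolerance = 1e-9)
  }
})

test_that("adduct m/z reproduces the characterized exact masses", {
  # [M-H]- of FA 18:1-OOH and [M+Na]+ of its 2-MxP derivative
  expect_identical(
    adductMz(monoisotopicMass(parseSpecies("FA 18:1-OOH")), "[M-H]-"),
    313.2384)
  expect_identical(
    adductMz(monoisotopicMass(parseSpecies("FA 18:1-OOMxP")),
             "[M+Na]+"),
    409.2924)
  # unicode minus accepted
  expect_identical(
    adductMz(monoisotopicMass(parseSpecies("FA 18:1-OOH")),
             "[M−H]−"),
    313.2384)
  expect_error(adductMz(100, "[M+K]+"), "unknown adduct")
  expect_error(adductMz(-1, "[M+Na]+"), "> 0")
})

test_that("proton gain/loss adducts are symmetric about the neutral mass", {
  for (x in c(100, 314.24571, 1000)) {
    d <- adductMz(x, "[M+H]+", digits = NULL) -
      adductMz(x, "[M-H]-", digits = NULL)
    expect_equal(d, 2 * 1.00782503 - 2 * ELECTRON, tolerance = 1e-12)
  }
})

test_that("sodiated OOMxP masses agree with the oracle for all 8 assayed species", {
  table1 <- list(c(18, 3), c(18, 2), c(18, 1), c(19, 1),
                 c(20, 5), c(20, 4), c(22, 6), c(22, 1))
  for (cd in table1) {
    n <- cd[1]; db <- cd[2]
    sp <- FattyAcylSpecies(n, db, "OOMxP")
    # OOMxP neutral: C_(n+4) H_(2n-2db+8) O5
    expected <- oracleMass(n + 4, 2 * n - 2 * db + 8, 5, nNa = 1) -
      ELECTRON
    expect_equal(adductMz(monoisotopicMass(sp), "[M+Na]+",
                          digits = NULL),
                 expected, tolerance = 1e-4)
  }
})

test_that("ppm error matches reported mass accuracies and is well behaved", {
  expect_identical(ppmError(409.2917, 409.2924), -1.71)
  expect_identical(ppmError(313.2384, 313.2384), 0)
  for (x in c(1, 409.2924, 2000)) {
    expect_identical(ppmError(x, x), 0)
    for (k in c(-5, 0.5, 3)) {
      expect_equal(ppmError(x * (1 + k * 1e-6), x, digits = NULL), k,
                   tolerance = 1e-3)
    }
  }
  expect_error(ppmError(100, 0), "> 0")
})
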