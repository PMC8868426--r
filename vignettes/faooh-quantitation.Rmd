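---
title: "Methods: targeted SRM quantitation of fatty acid hydroperoxides"
author: "faoohquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted SRM quantitation of fatty acid hydroperoxides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faoohquant)
```

## The assay

Fatty acid hydroperoxides (FAOOH) carry an -OOH group allylic to a
double bond. They are unstable and ionize poorly, so the assay this
package supports measures them as 2-methoxypropene (2-MxP) perketal
derivatives (FAOOMxP): the enol ether adds across the -OOH group, which
adds C4H8O (72.0575 Da) to the molecule, stabilizes it, and gives a
strong sodiated ion `[M+Na]+` in positive mode. Quantitation runs on a
triple quadrupole in selected reaction monitoring (SRM): one fixed
precursor/product m/z pair per analyte, an FA 19:1 hydroperoxide
internal standard (IS) spiked at constant amount before extraction, and
analyte responses normalized to the IS peak area.

The package covers the computational side end to end: mass arithmetic,
transition design, synthetic chromatograms with known ground truth,
peak integration, and the validation arithmetic (calibration, LOD/LOQ,
recovery, matrix effect, CV, concentration reporting).

## Mass arithmetic

Neutral formulas follow the derivatization ladder

* free acid: `C_n H_(2n - 2 db) O2`
* hydroperoxide: `+ O2`
* 2-MxP perketal: `+ C4H8O`

with monoisotopic masses pinned to C = 12 exactly, H = 1.00782503,
O = 15.99491462, Na = 22.98976928 and an electron mass of 0.00054858 Da.
Adduct deltas include the electron correction; without it the sodiated
and deprotonated exact masses miss the reference values at the fourth
decimal. Reporting uses 4 decimals in the high-resolution context and
1 decimal in the SRM context, rounded half away from zero.

```{r masses}
adductMz(monoisotopicMass(parseSpecies("FA 18:1-OOH")), "[M-H]-")
adductMz(monoisotopicMass(parseSpecies("FA 18:1-OOMxP")), "[M+Na]+")
ppmError(409.2917, 409.2924)
```

## Transition rules and the registry

Fragmentation of FAOOMxP is unsaturation-dependent. Poly-unsaturated
species (db >= 2) lose the nominal MxP unit, 72.0 Da; mono-unsaturated
species lose 202.1 Da, an empirical constant (the mean of the observed
201.9/202.1/202.1 parent-product differences). The chemical identity of
the 202.1 Da loss is not established; we treat it strictly as an
empirical rule and do not guess the fragment chemistry.

The packaged registry (`buildRegistry()`) ships the eight
instrument-tuned channels and is authoritative for acquisition and
matching; theoretical predictions are advisory QC. Tuned m/z deviate
from theory by up to ~0.13 Da before rounding, so
`validateAgainstRegistry()` defaults to a 0.2 Da tolerance -- wide
enough for tuning offsets, far below the 2.0 Da minimum spacing between
neighboring channels. Deviations are compared after rounding
predictions to the registry's 1-decimal convention (with a 1e-6 guard
so a deviation of exactly 0.2 is not lost to float error).

```{r registry}
validateAgainstRegistry(buildRegistry())
```

## The synthetic-data generator

`SimScenario()` parameterizes the generator; all randomness derives
from its mandatory seed (per-trace streams are keyed by sample and
species, so results do not depend on generation order). A trace is

```
intensity(t) = baseline + drift * t
             + amplitude * sigma * sqrt(2*pi) * shape(t; RT, sigma, tau)
             + N(0, noiseSd),   clamped at zero counts
```

with `amplitude = concentration * responseFactor * matrixMultiplier`.
Shapes have unit area, so the Gaussian's `amplitude` is the peak height
and the area is `amplitude * sigma * sqrt(2*pi)` for both the Gaussian
and the exponentially modified Gaussian (computed in log space for
stability). Defaults, chosen once as typical for a fast UHPLC
triple-quadrupole assay of this kind:

| parameter | default | rationale |
|---|---|---|
| run length | 6 min | separation completes within 6 min |
| retention times | evenly spaced 1.5-5.5 min | elution order known, exact RTs are not; configurable per species |
| peak sigma | 0.05 min (3 s) | sub-2 um column, 6-min gradient |
| sampling rate | 5 points/s | typical SRM dwell cycling; no published value |
| baseline / noise | 50 / 5 counts | low-count baseline with visible noise |
| IS concentration | 10 pmol/uL | 10 uL of 100 uM IS brought to a 100 uL final extract |
| response factor | 1000 counts per pmol/uL | puts the 0.01-100 pmol/uL grid across the dynamic range |
| replicate CV | 5% | mid-range of reported standard CVs (1-13%) |
| recovery fraction | 0.70 | center of the reported 48-76% recovery range |
| calibration grid | 0.01, 0.1, 1, 2.5, 5, 7.5, 10, 25, 50, 100 pmol/uL | the assay's dilution series |

Replicate (sample-prep) variability is a lognormal multiplier with mean
1, drawn **once per sample and shared by analytes and IS**. This is
deliberate: the IS is added before extraction, so preparation and
injection variability scale analyte and IS together -- exactly the
error the IS ratio cancels. Drawing per-trace instead would make
IS-normalized results *noisier* than raw areas and defeat the point of
the design. Raw peak areas still show the full replicate CV; the
`simulateReplicates()` day layer adds a shared per-day multiplier for
inter-day studies. The generator emits a ground-truth ledger
(`groundTruth()`) alongside every sample set; estimators read only the
design metadata (`sampleInfo()`: nominal levels, roles, days), never
the ledger.

What the generator does *not* emulate: co-eluting interferences,
retention-time drift between runs, detector saturation, carryover, and
isotope patterns. Passing tests therefore demonstrate correctness of
the arithmetic and estimators under the stated noise model, not
robustness to every real-data pathology.

## Peak detection and integration

For a trace and an expected-RT window (default +/- 0.3 min; peaks are
baseline-resolved well within that):

1. **Baseline**: a straight line through robust anchors (median time,
   median intensity) of the flanking peak-free regions. With a linear
   drift this reproduces the baseline exactly in the noise-free limit.
2. **Apex**: maximum of the smoothed (moving average, window 5),
   baseline-subtracted signal inside the window. Smoothing is used only
   for apex/boundary finding; integration uses raw intensities so areas
   stay unbiased.
3. **Boundaries**: walk outward from the apex to the first point that
   is both at/below 5% of the height *and* a local minimum, or to the
   window edge. On a noise-free peak the walk reaches the window edge
   (a pure 5%-crossing stop would discard 1.4% of a Gaussian's area; the
   local-minimum condition keeps noise-free areas accurate to <1% while
   noisy boundaries still settle near the 5% crossing).
4. **Noise**: 1.4826 times the *upper-sided* median absolute deviation
   of the baseline-subtracted signal outside the peak. For symmetric
   noise this equals the ordinary MAD; the one-sided form is immune to
   the zero clamp on counts, which at high noise censors the lower tail
   and would otherwise collapse a two-sided MAD to ~0 and declare
   everything detected.
5. **Decision**: detected iff S/N = height/noise >= `minSnr` (default
   3). Zero-noise traces cap S/N at 1e6 with a `zero_noise` flag rather
   than dividing by zero. Undetected traces report zero height/area
   with a `no_peak` flag.

## Validation arithmetic

* **Calibration**: OLS of response vs concentration over prepared
  levels at/above the LOQ (>= 4 usable levels required). The default
  response is the analyte/IS area ratio; absolute areas are available.
  Which response scale the reference slopes used is not stated
  anywhere, so both modes exist and the ratio -- standard practice with
  an internal standard -- is the default.
* **LOD / LOQ**: lowest prepared level whose median replicate S/N
  reaches 3 (LOD) or 10 (LOQ). Values snap to the prepared grid; there
  is no S/N interpolation, matching how reported limits sit exactly on
  grid points. If no level qualifies, `Inf` is the sentinel.
* **Recovery**: `100 * area(spiked sample) / area(spiked extract)`,
  replicate mean +/- SD. **Matrix effect**:
  `100 * area(spiked extract) / area(neat standard)`; < 100% is ion
  suppression, > 100% enhancement.
* **CV**: `100 * sd/mean`; intraday = mean of within-day CVs, interday
  = CV of daily means (>= 3 replicates per group, >= 3 days).
* **Quantitation**: `(response - intercept)/slope` in pmol/uL of final
  extract, gated on an IS peak at S/N >= 10 (otherwise the sample fails
  QC and emits no concentrations). Results are graded `ND` (undetected
  or below LOD), `<LOQ`, `at_LOQ`, `extrapolated` (outside the fitted
  range -- flagged, not refused, so survey-style reporting stays
  possible) or `ok`. A configured dilution chain (e.g. 50 uL serum
  brought to a 100 uL extract) back-calculates to source units.

## Numerical choices and tie-breaks

* Half-away-from-zero rounding (base `round()` is half-even), with a
  1e-9 relative nudge so values printed as exact halves round away
  from zero.
* LOD/LOQ comparisons and the `at_LOQ`/`ND` grading use a 1e-9 relative
  epsilon so a response mathematically *at* the limit is not pushed
  below it by float error.
* The calibration-slope recovery check uses a scenario in which the
  analyte co-elutes with the IS (the assay's chromatography co-elutes
  analytes and IS within the same short window) and the IS is scaled so
  the generative area-ratio slope equals the analyte response factor;
  with identical RT/width the boundary-truncation fraction cancels in
  the ratio and the fitted slope reproduces the response factor to
  machine precision.
* Degenerate inputs: empty formulas have mass 0; saturated species
  refuse hydroperoxide states; empty windows, even smoothing windows,
  zero denominators and sub-4-level calibrations raise informative
  errors rather than returning silent values.

## Problem sizes used by the test suite

Simulated checks run at desk scale, chosen so the full suite completes
in well under a minute: traces of 1801 points (6 min at 5 points/s),
ten-level calibration series, 5-6 replicates for validation triples,
n = 100 replicates for CV recovery, 100 seeded traces for the
apex-oracle comparison, 60 seeded runs for the R-squared coverage
check, and a five-rung noise ladder (noise SD 2 to 20 000 counts) for
LOD/LOQ monotonicity.

## Known limitations

* Only singly charged `[M-H]-`, `[M+H]+`, `[M+Na]+` adducts; no isotope
  patterns; no positional (regio-)isomer enumeration of the -OOH group.
* The 202.1 Da mono-unsaturated loss is an empirical constant, not a
  mechanistic model; the registry's tuned values remain authoritative.
* Overlapping peaks are not deconvolved and retention-time alignment
  across batches is out of scope.
* The S/N definition (smoothed height over one-sided MAD noise) is a
  documented package choice; instrument software may define S/N
  differently, so absolute LOD/LOQ values are comparable only within
  this definition.
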