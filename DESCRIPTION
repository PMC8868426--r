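Package: faoohquant
Title: Targeted SRM Quantitation of Fatty Acid Hydroperoxides as
    2-Methoxypropene Derivatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for targeted LC-MS/MS quantitation of fatty acid
    hydroperoxides (FAOOH) analyzed as 2-methoxypropene (2-MxP) perketal
    derivatives in positive-mode selected reaction monitoring (SRM).
    Provides in-silico derivatization and exact-mass arithmetic (adduct
    m/z, ppm error), unsaturation-dependent SRM transition prediction
    with a packaged default assay registry, a seeded synthetic
    chromatogram simulator with ground-truth ledgers, chromatographic
    peak detection and integration with robust noise estimation, and the
    full method-validation arithmetic: calibration curves, LOD/LOQ by
    signal-to-noise, recovery, matrix effect, coefficients of variation,
    and internal-standard-normalized concentration reporting.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    mzR,
    pracma,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'chem.R'
    'transitions.R'
    'simulate.R'
    'io.R'
    'peaks.R'
    'quant.R'
    'cli.R'
    'faoohquant-package.R'
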