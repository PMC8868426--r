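# Shared scenario builders for the test suite.

# Single-analyte scenario in which the analyte co-elutes with the
# internal standard (the assay's chromatography co-elutes analytes and
# IS) and the IS is scaled so that the generative area-ratio slope
# equals the analyte response factor exactly: slope = RF_a / (c_IS *
# RF_IS) with c_IS * RF_IS = 1 in response-factor units.
coelutionScenario <- function(seed, rf = 0.0022, scaleUnits = 1e5,
                              noiseSd = 0, replicateCv = 0, ...) {
  species <- "FA 18:2-OOMxP"
  SimScenario(
    seed = seed, species = species,
    responseFactor = rf * scaleUnits,
    isConcentration = 10, isResponseFactor = scaleUnits / 10,
    noiseSd = noiseSd, replicateCv = replicateCv,
    retentionTime = stats::setNames(c(3, 3),
                                    c(species, "FA 19:1-OOMxP")),
    ...)
}

# One-analyte scenario with defaults otherwise.
oneAnalyteScenario <- function(seed, ...) {
  SimScenario(seed = seed, species = "FA 18:2-OOMxP", ...)
}

# Key used by SampleSet/readers to index traces.
.traceKeyForTest <- function(sampleId, species)
  paste(sampleId, species, sep = "||")

# Expected Gaussian peak area in intensity*seconds for an amplitude
# (peak height) and sigma in minutes.
gaussArea <- function(amplitude, sigmaMin) {
  amplitude * sigmaMin * 60 * sqrt(2 * pi)
}
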