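# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# division rates of the reference circuit at balanced induction (10 ng/ml),
# no antibiotic: instantaneous fitness at the subpopulation mean fluorescences
referenceDivisionRates <- function() {
  tox <- atcToxicity()
  spec <- circuitMixtureSpec(10)
  mL <- spec@lowMode * exp((spec@logSdLow * log(10))^2 / 2)
  mH <- spec@highMode * exp((spec@logSdHigh * log(10))^2 / 2)
  c(gL = tox@g0 * gammaAtc(mL, 10, tox),
    gH = tox@g0 * gammaAtc(mH, 10, tox))
}

# stationary circuit distributions over an ATc panel (1e5 events each)
circuitDistributions <- function() {
  if (is.null(.fixtures$dists)) {
    atcLv <- c(0, 1, 2, 4, 10, 20)
    .fixtures$atcLevels <- atcLv
    .fixtures$dists <- lapply(atcLv, function(C) buildHistogram(
      generateStationaryEvents(circuitMixtureSpec(C, 1e5), seed = 70 + C,
                               atc = C)))
  }
  list(atc = .fixtures$atcLevels, dists = .fixtures$dists)
}

# small hand-made distribution: breaks and counts given explicitly
toyDistribution <- function(breaks, counts, smoothed = counts, window = 32) {
  new("FluorescenceDistribution", breaks = breaks,
      counts = as.numeric(counts), smoothed = as.numeric(smoothed),
      smoothWindow = window, dropped = 0, massChange = 0, atc = 0,
      zeocin = 0)
}
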