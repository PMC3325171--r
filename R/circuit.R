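# The calibrated reference circuit: a bistable positive-feedback construct in
# yeast whose inducer (ATc) dose-response, expression modes and switching
# rates emulate the characterized system. These defaults define the study
# conditions used by the synthetic generators and the benchmark.

#' Dose-response of the high-expressor fraction of the reference circuit
#'
#' Below the bistability threshold (1 ng/ml ATc) expression is unimodal low;
#' above it, the fraction of cells in the high expression mode rises along a
#' Hill curve that is balanced (about 1:1 subpopulations) at 10 ng/ml and
#' approaches 0.95 at saturating inducer.
#'
#' @param atc ATc concentration(s), ng/ml.
#' @return Fraction of cells in the high mode, in [0, 0.95].
#' @examples
#' circuitFractionHigh(c(0, 1, 10, 50))
#' @export
circuitFractionHigh <- function(atc) {
  stopifnot(all(atc >= 0))
  ifelse(atc >= 1, 0.95 * atc^1.8 / (10^1.8 + atc^1.8), 0)
}

#' Stationary fluorescence mixture of the reference circuit at one dose
#'
#' Expression modes sit at 8 a.u. (low) and 300 a.u. (high), about 1.6
#' decades apart, so the inter-mode valley lies near 50 a.u. - the constant
#' classification threshold used throughout.
#'
#' @param atc ATc concentration, ng/ml.
#' @param nEvents number of cells to draw.
#' @return A [MixtureSpec-class].
#' @export
circuitMixtureSpec <- function(atc, nEvents = 1e5) {
  mixtureSpec(lowMode = 8, highMode = 300, logSdLow = 0.18, logSdHigh = 0.22,
              fractionHigh = circuitFractionHigh(atc), nEvents = nEvents)
}

#' Measured switching rates of the reference circuit at balanced induction
#'
#' Rising and falling rates fitted from sorting-relaxation experiments at
#' 10 ng/ml ATc: r = 28.5e-3 per hour (low to high) and f = 0.7e-3 per hour
#' (high to low). These serve as generating truth for recovery studies and
#' for lineage-occupancy calculations.
#'
#' @return Named numeric vector with elements \code{r} and \code{f} (per hour).
#' @export
referenceSwitchingRates <- function() c(r = 28.5e-3, f = 0.7e-3)

#' Default classification threshold between low and high expressors
#'
#' @return 50 fluorescence a.u.
#' @export
defaultThreshold <- function() 50
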