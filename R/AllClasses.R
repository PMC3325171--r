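#' @import methods
NULL

# ---------------------------------------------------------------------------
# Single-cell event data
# ---------------------------------------------------------------------------

#' Single-cell cytometry events for one condition
#'
#' Container for per-cell measurements from one culture: reporter fluorescence
#' (FL1) plus forward and side scatter, together with the environmental
#' condition the culture was grown in (inducer and antibiotic concentrations).
#'
#' @slot exprs numeric matrix with columns \code{FSC}, \code{SSC}, \code{FL1};
#'   one row per cell. All values must be positive (log-transformable).
#' @slot atc anhydrotetracycline (ATc) concentration, ng/ml.
#' @slot zeocin extracellular Zeocin concentration, mg/ml.
#'
#' @seealso [eventTable()], [gateEvents()], [buildHistogram()]
#' @export
setClass("EventTable",
  representation(exprs = "matrix", atc = "numeric", zeocin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(colnames(object@exprs), c("FSC", "SSC", "FL1")))
      msg <- c(msg, "exprs must have columns FSC, SSC, FL1")
    if (any(!is.finite(object@exprs)))
      msg <- c(msg, "all event values must be finite")
    if (length(object@atc) != 1L || object@atc < 0)
      msg <- c(msg, "atc must be a single non-negative number")
    if (length(object@zeocin) != 1L || object@zeocin < 0)
      msg <- c(msg, "zeocin must be a single non-negative number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an EventTable
#'
#' @param fl1,fsc,ssc numeric vectors of equal length: fluorescence, forward
#'   scatter and side scatter per cell (arbitrary units, positive).
#' @param atc,zeocin condition: ATc (ng/ml) and Zeocin (mg/ml).
#' @return An [EventTable-class] object.
#' @examples
#' ev <- eventTable(fl1 = c(10, 200), fsc = c(100, 120), ssc = c(80, 90))
#' nEvents(ev)
#' @export
eventTable <- function(fl1, fsc = rep(100, length(fl1)),
                       ssc = rep(100, length(fl1)), atc = 0, zeocin = 0) {
  stopifnot(length(fl1) == length(fsc), length(fl1) == length(ssc))
  m <- cbind(FSC = as.numeric(fsc), SSC = as.numeric(ssc),
             FL1 = as.numeric(fl1))
  new("EventTable", exprs = m, atc = as.numeric(atc),
      zeocin = as.numeric(zeocin))
}

#' @describeIn eventTable number of events (cells)
#' @param x an \code{EventTable}
#' @export
nEvents <- function(x) nrow(x@exprs)

#' @describeIn eventTable fluorescence (FL1) vector
#' @export
fluorescence <- function(x) x@exprs[, "FL1"]

#' @describeIn eventTable scatter channels as a two-column matrix (FSC, SSC)
#' @export
scatterChannels <- function(x) x@exprs[, c("FSC", "SSC"), drop = FALSE]

#' @describeIn eventTable condition as named vector (atc, zeocin)
#' @export
condition <- function(x) c(atc = x@atc, zeocin = x@zeocin)

setMethod("show", "EventTable", function(object) {
  cat("EventTable:", nrow(object@exprs), "events |",
      "ATc", object@atc, "ng/ml, Zeocin", object@zeocin, "mg/ml\n")
  fl <- object@exprs[, "FL1"]
  cat("  FL1 range:", signif(min(fl), 3), "-", signif(max(fl), 3), "a.u.\n")
})

# ---------------------------------------------------------------------------
# Binned fluorescence distributions
# ---------------------------------------------------------------------------

#' Binned fluorescence distribution
#'
#' Histogram of reporter fluorescence on log-spaced, half-open bins
#' \code{[lo, hi)}, optionally smoothed. The normalized probability mass
#' \code{p(F)} (one value per bin, summing to 1) weights the fast-switching
#' overall-fitness average, and the smoothed counts enter the cellular-current
#' memory estimator.
#'
#' @slot breaks bin edges, length nbins + 1, strictly increasing, positive.
#' @slot counts raw event counts per bin.
#' @slot smoothed smoothed counts (length 0 until a smoother is applied).
#' @slot smoothWindow moving-average window used for smoothing (0 if none);
#'   the Poisson variance model of the bimodality z-test divides by this.
#' @slot dropped number of events discarded (non-positive or out of range).
#' @slot massChange \code{sum(smoothed) - sum(counts)} (edge effects).
#' @slot atc,zeocin condition of the culture the events came from.
#' @export
setClass("FluorescenceDistribution",
  representation(breaks = "numeric", counts = "numeric", smoothed = "numeric",
                 smoothWindow = "numeric", dropped = "numeric",
                 massChange = "numeric", atc = "numeric", zeocin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(diff(object@breaks) <= 0) || any(object@breaks <= 0))
      msg <- c(msg, "breaks must be positive and strictly increasing")
    if (length(object@counts) != length(object@breaks) - 1L)
      msg <- c(msg, "counts length must equal number of bins")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (length(object@smoothed) &&
        length(object@smoothed) != length(object@counts))
      msg <- c(msg, "smoothed length must equal counts length")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn FluorescenceDistribution geometric bin centers (a.u.)
#' @param x a \code{FluorescenceDistribution}
#' @export
binCenters <- function(x) sqrt(x@breaks[-1] * x@breaks[-length(x@breaks)])

#' @describeIn FluorescenceDistribution bin widths (a.u.)
#' @export
binWidths <- function(x) diff(x@breaks)

#' @describeIn FluorescenceDistribution raw counts per bin
#' @export
binCounts <- function(x) x@counts

#' @describeIn FluorescenceDistribution smoothed counts (error if absent)
#' @export
smoothedCounts <- function(x) {
  if (!length(x@smoothed)) stop("distribution has not been smoothed")
  x@smoothed
}

#' @describeIn FluorescenceDistribution normalized probability mass per bin,
#'   summing to one; computed from smoothed counts when \code{smoothed = TRUE}
#' @param smoothed use the smoothed counts?
#' @export
probMass <- function(x, smoothed = FALSE) {
  cnt <- if (smoothed) smoothedCounts(x) else x@counts
  tot <- sum(cnt)
  if (tot <= 0) stop("empty distribution: total count is zero")
  cnt / tot
}

setMethod("show", "FluorescenceDistribution", function(object) {
  n <- length(object@counts)
  cat("FluorescenceDistribution:", n, "log-spaced bins over [",
      signif(object@breaks[1], 3), ",", signif(object@breaks[n + 1], 3),
      ") a.u.;", sum(object@counts), "events",
      if (length(object@smoothed)) sprintf("(smoothed, window %g)",
                                           object@smoothWindow) else "",
      "\n")
})

# ---------------------------------------------------------------------------
# Bimodality / subpopulations
# ---------------------------------------------------------------------------

#' Result of the histogram bimodality test
#'
#' A smoothed histogram is declared bimodal when some interior local minimum
#' lies more than \code{zCutoff} standard deviations below the largest smoothed
#' count on each side, under the Poisson variance model
#' var = expectation / window.
#'
#' @slot isBimodal logical.
#' @slot candidates fluorescence (a.u.) of accepted valley candidates.
#' @slot zLeft,zRight z-scores of each candidate against the flanking maxima.
#' @slot threshold selected threshold (a.u.); \code{NA} when not bimodal.
#' @export
setClass("BimodalityResult",
  representation(isBimodal = "logical", candidates = "numeric",
                 zLeft = "numeric", zRight = "numeric", threshold = "numeric"))

setMethod("show", "BimodalityResult", function(object) {
  if (object@isBimodal)
    cat("BimodalityResult: bimodal;", length(object@candidates),
        "candidate threshold(s); selected", signif(object@threshold, 4),
        "a.u.\n")
  else cat("BimodalityResult: not bimodal\n")
})

#' Subpopulation summary for a thresholded event table
#'
#' @slot nLow,nHigh cell counts below / at-or-above the threshold.
#' @slot ratio subpopulation ratio R = nLow / nHigh (Inf-flagged if nHigh = 0).
#' @slot ratioInfinite TRUE when nHigh = 0.
#' @slot meanLow,meanHigh,meanAll arithmetic mean fluorescence (a.u.).
#' @slot cv coefficient of variation of all events (population SD convention).
#' @slot threshold the threshold used (a.u.).
#' @export
setClass("SubpopulationSummary",
  representation(nLow = "numeric", nHigh = "numeric", ratio = "numeric",
                 ratioInfinite = "logical", meanLow = "numeric",
                 meanHigh = "numeric", meanAll = "numeric", cv = "numeric",
                 threshold = "numeric"))

setMethod("show", "SubpopulationSummary", function(object) {
  cat(sprintf(
    "SubpopulationSummary (theta = %g a.u.): N_L = %g, N_H = %g, R = %s\n",
    object@threshold, object@nLow, object@nHigh,
    if (object@ratioInfinite) "Inf (no high expressors)"
    else signif(object@ratio, 4)))
  cat(sprintf("  mean = %.4g a.u., CV = %.4g\n", object@meanAll, object@cv))
})

# ---------------------------------------------------------------------------
# Growth curves and fitness estimates
# ---------------------------------------------------------------------------

#' Growth curve for one condition
#'
#' @slot times hours, strictly increasing, at least two points.
#' @slot counts cells/ml, positive.
#' @slot atc,zeocin condition.
#' @export
setClass("GrowthCurve",
  representation(times = "numeric", counts = "numeric", atc = "numeric",
                 zeocin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) < 2L) msg <- c(msg, "need at least 2 points")
    if (length(object@times) != length(object@counts))
      msg <- c(msg, "times and counts must have equal length")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(object@counts <= 0)) msg <- c(msg, "counts must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname GrowthCurve-class
#' @param times,counts,atc,zeocin see slots
#' @export
growthCurve <- function(times, counts, atc = 0, zeocin = 0) {
  new("GrowthCurve", times = as.numeric(times), counts = as.numeric(counts),
      atc = as.numeric(atc), zeocin = as.numeric(zeocin))
}

setMethod("show", "GrowthCurve", function(object) {
  cat("GrowthCurve:", length(object@times), "points over",
      max(object@times) - min(object@times), "h | ATc", object@atc,
      "ng/ml, Zeocin", object@zeocin, "mg/ml\n")
})

#' Fitness (growth-rate) estimate
#'
#' @slot g growth rate, per hour.
#' @slot se standard error, per hour.
#' @slot method "pointwise" or "linear_fit".
#' @slot nPointsUsed number of curve points entering the estimate.
#' @export
setClass("FitnessEstimate",
  representation(g = "numeric", se = "numeric", method = "character",
                 nPointsUsed = "numeric"),
  validity = function(object)
    if (length(object@se) && !is.na(object@se) && object@se < 0)
      "standard error must be non-negative" else TRUE)

setMethod("show", "FitnessEstimate", function(object) {
  cat(sprintf("FitnessEstimate (%s): g = %.5g +/- %.2g per hour (n = %d)\n",
              object@method, object@g, object@se, object@nPointsUsed))
})

# ---------------------------------------------------------------------------
# Two-state model
# ---------------------------------------------------------------------------

#' Parameters of the two-state switching population model
#'
#' Low-state cells divide at rate \code{gL} and rise into the high state at
#' rate \code{r}; high-state cells divide at \code{gH} and fall back at
#' \code{f}. All rates are per hour.
#'
#' @slot r,f switching (rising / falling) rates, per hour, non-negative.
#' @slot gL,gH state division rates, per hour.
#' @export
setClass("TwoStateParams",
  representation(r = "numeric", f = "numeric", gL = "numeric", gH = "numeric"),
  validity = function(object) {
    msg <- NULL
    v <- c(object@r, object@f, object@gL, object@gH)
    if (length(v) != 4L || any(!is.finite(v)))
      msg <- c(msg, "all four rates must be single finite numbers")
    else if (object@r < 0 || object@f < 0)
      msg <- c(msg, "switching rates r and f must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname TwoStateParams-class
#' @param r,f,gL,gH rates per hour
#' @export
twoStateParams <- function(r, f, gL = 0, gH = 0)
  new("TwoStateParams", r = as.numeric(r), f = as.numeric(f),
      gL = as.numeric(gL), gH = as.numeric(gH))

setMethod("show", "TwoStateParams", function(object) {
  cat(sprintf(
    "TwoStateParams: r = %.4g, f = %.4g, gL = %.4g, gH = %.4g per hour\n",
    object@r, object@f, object@gL, object@gH))
})

#' Spectral solution of the two-state model
#'
#' Eigen-decomposition of the 2x2 rate matrix
#' \code{[[gL - r, f], [r, gH - f]]}. The dominant eigenvalue \code{a1} is the
#' asymptotic population growth rate; the closed-form subpopulation ratio
#' R(t) = N_L(t)/N_H(t) is available through [ratioTrajectory()].
#'
#' @slot a1,a2 eigenvalues, per hour, a1 >= a2 (a1 real).
#' @slot vectors 2x2 matrix of right eigenvectors (columns, order a1, a2).
#' @slot params the generating \code{TwoStateParams}.
#' @export
setClass("SpectralSolution",
  representation(a1 = "numeric", a2 = "numeric", vectors = "matrix",
                 params = "TwoStateParams"),
  validity = function(object)
    if (object@a1 < object@a2) "a1 must be >= a2" else TRUE)

setMethod("show", "SpectralSolution", function(object) {
  cat(sprintf("SpectralSolution: a1 = %.5g, a2 = %.5g per hour\n",
              object@a1, object@a2))
})

#' Sorting-relaxation time course
#'
#' Subpopulation ratios R(t) = N_L/N_H over time for three arms of a sorting
#' experiment: cells sorted into predominantly high expressors, predominantly
#' low expressors, and the unsorted control, all sharing one time grid.
#'
#' @slot times hours.
#' @slot highSorted,lowSorted,unsorted ratio R(t) per arm, positive.
#' @export
setClass("SortRelaxationData",
  representation(times = "numeric", highSorted = "numeric",
                 lowSorted = "numeric", unsorted = "numeric"),
  validity = function(object) {
    n <- length(object@times)
    msg <- NULL
    if (any(lengths(list(object@highSorted, object@lowSorted,
                         object@unsorted)) != n))
      msg <- c(msg, "all arms must share the time grid")
    pos <- object@times > 0
    if (any(c(object@highSorted, object@lowSorted, object@unsorted) < 0) ||
        any(c(object@highSorted[pos], object@lowSorted[pos],
              object@unsorted[pos]) <= 0))
      msg <- c(msg, "ratios must be positive (zero allowed only at time 0)")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SortRelaxationData", function(object) {
  cat("SortRelaxationData:", length(object@times), "time points over",
      max(object@times), "h (high-sorted, low-sorted, unsorted arms)\n")
})

# ---------------------------------------------------------------------------
# Stochastic simulation outputs
# ---------------------------------------------------------------------------

#' Trajectory of the stochastic birth-switch population
#'
#' @slot times record times, hours.
#' @slot nL,nH cell counts in low / high state at each record time.
#' @slot logDilution cumulative log of dilution factors applied up to each
#'   record time; \code{log(nL + nH) + logDilution} is the log of the
#'   undiluted population size.
#' @slot extinct TRUE if the population reached zero (trajectory truncated).
#' @export
setClass("PopulationTrajectory",
  representation(times = "numeric", nL = "numeric", nH = "numeric",
                 logDilution = "numeric", extinct = "logical"),
  validity = function(object) {
    msg <- NULL
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(object@nL < 0) || any(object@nH < 0))
      msg <- c(msg, "counts must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn PopulationTrajectory log total population size corrected for
#'   dilution
#' @param x a \code{PopulationTrajectory}
#' @export
logPopulation <- function(x) log(x@nL + x@nH) + x@logDilution

setMethod("show", "PopulationTrajectory", function(object) {
  cat("PopulationTrajectory:", length(object@times), "records over",
      max(object@times), "h",
      if (object@extinct) "(EXTINCT)" else "", "\n")
})

#' Single-cell lineage trace of the two-state switching process
#'
#' @slot switchTimes times of state changes, hours, increasing.
#' @slot states states visited (alternating "L"/"H"), one per sojourn,
#'   starting with the initial state; length = length(switchTimes) + 1.
#' @slot duration total simulated time, hours.
#' @slot degenerate TRUE when r = f = 0 (single state, no switching).
#' @export
setClass("LineageTrace",
  representation(switchTimes = "numeric", states = "character",
                 duration = "numeric", degenerate = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@states) != length(object@switchTimes) + 1L)
      msg <- c(msg, "states must have one more element than switchTimes")
    if (length(object@switchTimes) && any(diff(object@switchTimes) <= 0))
      msg <- c(msg, "switchTimes must be strictly increasing")
    if (length(object@states) > 1L &&
        any(object@states[-1] == object@states[-length(object@states)]))
      msg <- c(msg, "states must alternate")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "LineageTrace", function(object) {
  cat("LineageTrace:", length(object@switchTimes), "switches over",
      object@duration, "h; high-state occupancy",
      signif(occupancyHigh(object), 4),
      if (object@degenerate) "(degenerate: r = f = 0)" else "", "\n")
})

# ---------------------------------------------------------------------------
# Synthetic-data configuration
# ---------------------------------------------------------------------------

#' Two-component log-normal fluorescence mixture specification
#'
#' Describes a stationary fluorescence distribution as a mixture of a low and
#' a high expression mode, each log-normal on the log10 axis, with correlated
#' log-normal scatter channels. Emulates the steady-state histograms of a
#' bistable reporter circuit at one inducer concentration.
#'
#' @slot lowMode,highMode mode locations, fluorescence a.u. (> 0).
#' @slot logSdLow,logSdHigh mode widths, log10 decades.
#' @slot fractionHigh probability a cell is in the high mode, in [0, 1].
#' @slot nEvents number of cells to draw (>= 1).
#' @slot scatterLocation,scatterScale location (log10) and scale of the
#'   forward/side scatter model.
#' @export
setClass("MixtureSpec",
  representation(lowMode = "numeric", highMode = "numeric",
                 logSdLow = "numeric", logSdHigh = "numeric",
                 fractionHigh = "numeric", nEvents = "numeric",
                 scatterLocation = "numeric", scatterScale = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@fractionHigh < 0 || object@fractionHigh > 1)
      msg <- c(msg, "fractionHigh must lie in [0, 1]")
    if (object@lowMode <= 0 || object@highMode <= 0)
      msg <- c(msg, "mode locations must be positive")
    if (object@nEvents < 1) msg <- c(msg, "nEvents must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname MixtureSpec-class
#' @param lowMode,highMode,logSdLow,logSdHigh,fractionHigh,nEvents see slots
#' @param scatterLocation,scatterScale scatter model (log10 location, scale)
#' @export
mixtureSpec <- function(lowMode = 8, highMode = 300, logSdLow = 0.18,
                        logSdHigh = 0.22, fractionHigh = 0.5, nEvents = 1e5,
                        scatterLocation = 2.3, scatterScale = 0.12) {
  new("MixtureSpec", lowMode = lowMode, highMode = highMode,
      logSdLow = logSdLow, logSdHigh = logSdHigh, fractionHigh = fractionHigh,
      nEvents = nEvents, scatterLocation = scatterLocation,
      scatterScale = scatterScale)
}

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf(
    "MixtureSpec: modes %g / %g a.u. (log10 SD %g / %g), fractionHigh = %g, %g events\n",
    object@lowMode, object@highMode, object@logSdLow, object@logSdHigh,
    object@fractionHigh, object@nEvents))
})

#' Simulation bookkeeping configuration
#'
#' @slot seed integer RNG seed.
#' @slot duration total simulated time, hours (> 0).
#' @slot recordInterval sampling interval, hours; defaults to the 12-h
#'   resuspension cadence of the growth protocol.
#' @slot noiseCv multiplicative log-normal count-noise CV (>= 0).
#' @export
setClass("SimConfig",
  representation(seed = "integer", duration = "numeric",
                 recordInterval = "numeric", noiseCv = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (object@recordInterval <= 0)
      msg <- c(msg, "recordInterval must be positive")
    if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname SimConfig-class
#' @param seed,duration,recordInterval,noiseCv see slots
#' @export
simConfig <- function(duration = 72, recordInterval = 12, noiseCv = 0.1,
                      seed = 1L) {
  new("SimConfig", seed = as.integer(seed), duration = duration,
      recordInterval = recordInterval, noiseCv = noiseCv)
}

# ---------------------------------------------------------------------------
# Toxicity model parameters
# ---------------------------------------------------------------------------

#' Zeocin toxicity model parameters
#'
#' Parameters of the steady-state intracellular Zeocin model: the antibiotic
#' diffuses across the membrane at rate \code{hZ}, binds irreversibly to the
#' resistance protein at rate \code{s}, and the protein turns over at rate
#' \code{d}; fitness is reduced by the free intracellular antibiotic as
#' gamma1 = 1 / (1 + chi * Zi^phi).
#'
#' The kinetic constants act on intracellular copy-number-like scales;
#' concentrations in mg/ml and fluorescence in instrument a.u. are mapped to
#' that scale by the calibration factors \code{zeocinUnits} and
#' \code{fluorUnits} (model units per mg/ml and per a.u.).
#'
#' @slot phi toxicity exponent (dimensionless).
#' @slot chi toxicity coefficient (per model-unit^phi).
#' @slot s binding affinity of the resistance protein for the antibiotic.
#' @slot hZ membrane exchange rate.
#' @slot d resistance-protein degradation/dilution rate.
#' @slot zeocinUnits model units per mg/ml extracellular Zeocin.
#' @slot fluorUnits model units per fluorescence a.u.
#' @export
setClass("ZeocinToxicity",
  representation(phi = "numeric", chi = "numeric", s = "numeric",
                 hZ = "numeric", d = "numeric", zeocinUnits = "numeric",
                 fluorUnits = "numeric"),
  validity = function(object) {
    if (any(c(object@phi, object@chi, object@s, object@hZ, object@d,
              object@zeocinUnits, object@fluorUnits) < 0))
      "all parameters must be non-negative" else TRUE
  })

#' @rdname ZeocinToxicity-class
#' @param phi,chi,s,hZ,d,zeocinUnits,fluorUnits see slots
#' @export
zeocinToxicity <- function(phi = 1.182, chi = 0.5028e-7, s = 1.2732e6,
                           hZ = 0.5, d = 0.25, zeocinUnits = 5e6,
                           fluorUnits = 2e5) {
  new("ZeocinToxicity", phi = phi, chi = chi, s = s, hZ = hZ, d = d,
      zeocinUnits = zeocinUnits, fluorUnits = fluorUnits)
}

setMethod("show", "ZeocinToxicity", function(object) {
  cat(sprintf(
    "ZeocinToxicity: phi = %g, chi = %g, s = %g (hZ = %g, d = %g fixed)\n",
    object@phi, object@chi, object@s, object@hZ, object@d))
})

#' Inducer (ATc / transactivator) toxicity model parameters
#'
#' Activated transactivator molecules impose an expression-level-dependent
#' fitness cost: gamma2 = 1 / (1 + alpha * (F/fluorRef) * C/(beta + C)).
#'
#' @slot alpha toxicity of the activated transactivator (dimensionless after
#'   fluorescence normalization).
#' @slot beta inducer binding scale, ng/ml.
#' @slot g0 maximal fitness (no inducer, no antibiotic), per hour.
#' @slot fluorRef fluorescence normalization scale, a.u.
#' @export
setClass("AtcToxicity",
  representation(alpha = "numeric", beta = "numeric", g0 = "numeric",
                 fluorRef = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@alpha < 0 || object@beta < 0)
      msg <- c(msg, "alpha and beta must be non-negative")
    if (object@g0 <= 0) msg <- c(msg, "g0 must be positive")
    if (object@fluorRef <= 0) msg <- c(msg, "fluorRef must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname AtcToxicity-class
#' @param alpha,beta,g0,fluorRef see slots
#' @export
atcToxicity <- function(alpha = 936, beta = 5.8, g0 = 0.4, fluorRef = 1e6) {
  new("AtcToxicity", alpha = alpha, beta = beta, g0 = g0,
      fluorRef = fluorRef)
}

setMethod("show", "AtcToxicity", function(object) {
  cat(sprintf("AtcToxicity: alpha = %g, beta = %g ng/ml, g0 = %g per hour\n",
              object@alpha, object@beta, object@g0))
})

# ---------------------------------------------------------------------------
# Cellular currents and memory
# ---------------------------------------------------------------------------

#' Directional cellular currents through a fluorescence threshold
#'
#' @slot threshold the threshold theta, a.u.
#' @slot down downward current I_H->L, cells per hour (>= 0).
#' @slot up upward current I_L->H, cells per hour (>= 0).
#' @slot net net upward current, cells per hour (up - down).
#' @slot stationarityGap integral of (g(F) - g_T) p(F) over the full range;
#'   should vanish for a stationary distribution.
#' @export
setClass("CurrentEstimate",
  representation(threshold = "numeric", down = "numeric", up = "numeric",
                 net = "numeric", stationarityGap = "numeric"),
  validity = function(object) {
    if (object@down < 0 || object@up < 0) "currents must be non-negative"
    else TRUE
  })

setMethod("show", "CurrentEstimate", function(object) {
  cat(sprintf(
    "CurrentEstimate (theta = %g): I_down = %.4g, I_up = %.4g cells/h (net %.4g)\n",
    object@threshold, object@down, object@up, object@net))
})

#' Cellular memory of high and low expression states
#'
#' @slot tauL,tauH mean waiting times in low / high state, hours (may be Inf).
#' @slot threshold threshold used, a.u.
#' @slot atc,zeocin condition.
#' @slot conservative TRUE when smoothing filled empty bins above the
#'   threshold, so tauH is a conservative lower estimate.
#' @export
setClass("MemoryEstimate",
  representation(tauL = "numeric", tauH = "numeric", threshold = "numeric",
                 atc = "numeric", zeocin = "numeric",
                 conservative = "logical"),
  validity = function(object)
    if (any(c(object@tauL, object@tauH) < 0, na.rm = TRUE))
      "memories must be non-negative" else TRUE)

setMethod("show", "MemoryEstimate", function(object) {
  cat(sprintf(
    "MemoryEstimate (ATc %g): tauL = %.4g h, tauH = %.4g h%s\n",
    object@atc, object@tauL, object@tauH,
    if (object@conservative) " (tauH conservative lower bound)" else ""))
})

# ---------------------------------------------------------------------------
# Landscape
# ---------------------------------------------------------------------------

#' Predicted overall-fitness surface over (ATc, Zeocin)
#'
#' @slot atc ATc grid, ng/ml, ascending.
#' @slot zeocin Zeocin grid, mg/ml, ascending.
#' @slot values matrix of predicted overall fitness, per hour
#'   (rows = atc, cols = zeocin).
#' @slot mode "fast_switching" or "memory_aware".
#' @export
setClass("FitnessSurface",
  representation(atc = "numeric", zeocin = "numeric", values = "matrix",
                 mode = "character"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@atc, strictly = TRUE) ||
        is.unsorted(object@zeocin, strictly = TRUE))
      msg <- c(msg, "grids must be sorted ascending")
    if (!all(dim(object@values) == c(length(object@atc),
                                     length(object@zeocin))))
      msg <- c(msg, "values must be length(atc) x length(zeocin)")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (!object@mode %in% c("fast_switching", "memory_aware"))
      msg <- c(msg, "mode must be fast_switching or memory_aware")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "FitnessSurface", function(object) {
  cat(sprintf(
    "FitnessSurface (%s): %d ATc x %d Zeocin levels, g in [%.4g, %.4g] per hour\n",
    object@mode, length(object@atc), length(object@zeocin),
    min(object@values), max(object@values)))
})

#' Drug-resistance sweet spot on a fitness surface
#'
#' @slot atc,zeocin location of the optimum (on the evaluated grid).
#' @slot g fitness at the optimum, per hour.
#' @slot sharpness curvature proxy: negative discrete second difference of
#'   fitness along ATc at the optimum (NA on the grid boundary).
#' @slot boundary TRUE when the optimum sits on the grid boundary.
#' @slot flat TRUE when the slice is flat.
#' @export
setClass("SweetSpot",
  representation(atc = "numeric", zeocin = "numeric", g = "numeric",
                 sharpness = "numeric", boundary = "logical",
                 flat = "logical"))

setMethod("show", "SweetSpot", function(object) {
  cat(sprintf(
    "SweetSpot: ATc = %g ng/ml, Zeocin = %g mg/ml, g = %.4g per hour%s%s\n",
    object@atc, object@zeocin, object@g,
    if (object@boundary) " [boundary]" else "",
    if (object@flat) " [flat slice]" else ""))
})
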