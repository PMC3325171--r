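# Nongenetic memory estimation from stationary fluorescence distributions via
# directional cellular currents, with fitness corrections.

#' Downward cellular current through a threshold
#'
#' A stable reporter protein is lost mainly through dilution by growth, so
#' cells leave the high state by drifting down in fluorescence at speed
#' \eqn{\theta g} at the threshold. The downward current is
#' \deqn{I_{H \to L} = \theta \, g_0 \gamma_2(\theta, C) \,
#'       \partial N/\partial F |_{\theta^+},}
#' where the cell density immediately above the threshold is read from the
#' smoothed histogram (first bin fully above theta, counts / bin width).
#' Dilution is set by the inducer-marginal growth rate
#' \eqn{g_0\gamma_2(\theta, C)} because memory is estimated from
#' antibiotic-free stationary distributions.
#'
#' @param dist a smoothed [FluorescenceDistribution-class].
#' @param threshold theta, a.u.; must lie strictly inside the histogram
#'   range (not in an edge bin).
#' @param atc ATc concentration, ng/ml (defaults to the distribution's).
#' @param atcParams an [AtcToxicity-class].
#' @param g0 maximal fitness, per hour.
#' @return Downward current, cells per hour (0 when no density above theta).
#' @export
downwardCurrent <- function(dist, threshold = defaultThreshold(),
                            atc = dist@atc, atcParams = atcToxicity(),
                            g0 = atcParams@g0) {
  stopifnot(is(dist, "FluorescenceDistribution"))
  n <- length(dist@counts)
  i <- findInterval(threshold, dist@breaks) + 1L  # first bin fully above
  if (i <= 1L || i > n)
    stop("threshold must lie strictly inside the histogram range")
  dens <- smoothedCounts(dist)[i] / binWidths(dist)[i]  # cells per a.u.
  threshold * g0 * gammaAtc(threshold, atc, atcParams) * dens
}

#' Fitness-corrected cellular currents through a threshold
#'
#' In a stationary distribution with uniform fitness the upward and downward
#' currents cancel. When instantaneous fitness g(F) varies across the
#' distribution, cells produced in excess below the threshold must flow
#' upward (and vice versa): the net upward current equals
#' \deqn{I_{net} = \int_{F < \theta} (g(F) - g_T)\, N(F)\, dF,}
#' evaluated by trapezoidal quadrature over the binned density. The upward
#' current is then I_up = I_down + I_net (floored at zero).
#'
#' @param dist a smoothed [FluorescenceDistribution-class].
#' @param threshold theta, a.u.
#' @param fitnessFn function of fluorescence returning instantaneous fitness,
#'   per hour (e.g. \code{function(F) g0 * gammaAtc(F, atc)}).
#' @param gT overall population fitness, per hour; computed from the
#'   distribution and \code{fitnessFn} (trapezoidal average) when NULL.
#' @param dilutionRate dilution rate at the threshold for the downward
#'   current; defaults to \code{fitnessFn(threshold)}.
#' @param stationarityTol warn when the full-range integral of
#'   (g - gT) p(F) exceeds this (per hour): the distribution cannot be
#'   stationary under the supplied fitness.
#' @return A [CurrentEstimate-class] (currents in cells per hour).
#' @export
cellularCurrents <- function(dist, threshold = defaultThreshold(), fitnessFn,
                             gT = NULL, dilutionRate = NULL,
                             stationarityTol = 1e-6) {
  stopifnot(is(dist, "FluorescenceDistribution"), is.function(fitnessFn))
  fc <- binCenters(dist)
  wd <- binWidths(dist)
  sm <- smoothedCounts(dist)
  dens <- sm / wd                       # cells per a.u.
  gF <- fitnessFn(fc)
  wTrapz <- pracma::trapz(fc, dens)     # total cells under the trapezoid
  if (is.null(gT)) gT <- pracma::trapz(fc, gF * dens) / wTrapz
  gap <- pracma::trapz(fc, (gF - gT) * dens) / wTrapz
  if (abs(gap) > stationarityTol)
    warning(sprintf(
      "stationarity violated: mean fitness imbalance %.3g per hour", gap))
  net <- trapzMasked(fc, (gF - gT) * dens, fc < threshold)
  if (is.null(dilutionRate)) dilutionRate <- fitnessFn(threshold)
  i <- findInterval(threshold, dist@breaks) + 1L
  if (i <= 1L || i > length(sm))
    stop("threshold must lie strictly inside the histogram range")
  down <- threshold * dilutionRate * dens[i]
  up <- max(0, down + net)
  new("CurrentEstimate", threshold = threshold, down = down, up = up,
      net = net, stationarityGap = gap)
}

#' Cellular memory from currents: mean waiting times in each state
#'
#' If N_H cells occupy the high state and cells exit it at rate I_H->L, the
#' mean waiting time before an arbitrary high cell leaves is
#' tau_H = N_H / I_H->L (and symmetrically tau_L = N_L / I_L->H). A zero
#' current yields infinite memory (flagged, not an error).
#'
#' @param dist the [FluorescenceDistribution-class] the currents came from.
#' @param currents a [CurrentEstimate-class].
#' @param conservative set TRUE when smoothing filled empty bins above the
#'   threshold, making tau_H a conservative lower estimate.
#' @return A [MemoryEstimate-class] (hours).
#' @export
memoryFromCurrents <- function(dist, currents, conservative = NA) {
  stopifnot(is(dist, "FluorescenceDistribution"),
            is(currents, "CurrentEstimate"))
  theta <- currents@threshold
  hi <- binCenters(dist) >= theta
  nH <- sum(dist@counts[hi])
  nL <- sum(dist@counts[!hi])
  if (is.na(conservative)) {
    i <- findInterval(theta, dist@breaks) + 1L
    conservative <- dist@counts[i] == 0 && length(dist@smoothed) > 0
  }
  new("MemoryEstimate",
      tauL = if (currents@up > 0) nL / currents@up else Inf,
      tauH = if (currents@down > 0) nH / currents@down else Inf,
      threshold = theta, atc = dist@atc, zeocin = dist@zeocin,
      conservative = conservative)
}

#' One-call memory estimate for a stationary distribution
#'
#' Gaussian-smooths the histogram (bandwidth 2 bins, filling empty bins),
#' builds the antibiotic-free instantaneous fitness g(F) = g0 gamma2(F, C),
#' computes the fitness-corrected currents and converts them to memories.
#'
#' @param dist a [FluorescenceDistribution-class] (raw counts suffice).
#' @param threshold theta, a.u.
#' @param atcParams an [AtcToxicity-class].
#' @param g0 maximal fitness, per hour.
#' @param bandwidth Gaussian smoothing bandwidth, bins.
#' @return A [MemoryEstimate-class].
#' @export
estimateMemory <- function(dist, threshold = defaultThreshold(),
                           atcParams = atcToxicity(), g0 = atcParams@g0,
                           bandwidth = 2) {
  stopifnot(is(dist, "FluorescenceDistribution"))
  i <- findInterval(threshold, dist@breaks) + 1L
  rawEmpty <- i >= 1L && i <= length(dist@counts) && dist@counts[i] == 0
  sm <- smoothHistogram(dist, method = "gaussian", bandwidth = bandwidth)
  atc <- dist@atc
  fitnessFn <- function(F) g0 * gammaAtc(F, atc, atcParams)
  cur <- cellularCurrents(sm, threshold, fitnessFn)
  memoryFromCurrents(sm, cur, conservative = rawEmpty)
}

#' Memory dose-response across inducer levels
#'
#' Applies [estimateMemory()] to a set of stationary distributions measured
#' (or generated) at increasing inducer concentrations.
#'
#' @param dists list of [FluorescenceDistribution-class].
#' @param atcLevels ATc per distribution, ng/ml (defaults to the
#'   distributions' own annotation).
#' @param threshold theta, a.u.
#' @param atcParams,g0 as in [estimateMemory()].
#' @return Data frame with columns \code{atc}, \code{tauL}, \code{tauH},
#'   \code{conservative}.
#' @export
memoryDoseResponse <- function(dists, atcLevels = NULL,
                               threshold = defaultThreshold(),
                               atcParams = atcToxicity(), g0 = atcParams@g0) {
  if (is.null(atcLevels))
    atcLevels <- vapply(dists, function(d) d@atc, numeric(1))
  stopifnot(length(dists) == length(atcLevels))
  rows <- lapply(seq_along(dists), function(i) {
    d <- dists[[i]]
    d@atc <- atcLevels[i]
    m <- estimateMemory(d, threshold, atcParams, g0)
    data.frame(atc = atcLevels[i], tauL = m@tauL, tauH = m@tauH,
               conservative = m@conservative)
  })
  do.call(rbind, rows)
}
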