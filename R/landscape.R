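# Memory-aware prediction of the 2-D fitness landscape over (ATc, Zeocin),
# sweet-spot location, model comparison and selection reshaping.

#' Calibrate a two-state model from a Zeocin-free stationary distribution
#'
#' Builds the condition-specific [TwoStateParams-class] used by the
#' memory-aware landscape predictor: switching rates are the reciprocal
#' cellular memories estimated from the distribution ([estimateMemory()]),
#' and the state division rates are the joint instantaneous fitness
#' evaluated at the representative (mean) fluorescence of each
#' subpopulation, g_X = g0 gamma1(F_X, Z) gamma2(F_X, C). When the
#' distribution has no high-expressor mass above the threshold the condition
#' is treated as single-state (r = f = 0, all mass low).
#'
#' @param dist a [FluorescenceDistribution-class] measured (or generated) at
#'   Zeocin = 0.
#' @param atc inducer level of the distribution, ng/ml.
#' @param zeocin antibiotic level to predict at, mg/ml.
#' @param zeoParams,atcParams toxicity parameters.
#' @param g0 maximal fitness, per hour.
#' @param threshold classification threshold, a.u.
#' @return List with \code{params} ([TwoStateParams-class]),
#'   \code{fractionHigh}, \code{meanLow}, \code{meanHigh}, \code{memory}
#'   (the [MemoryEstimate-class] or NULL), and \code{singleState}.
#' @export
calibrateTwoState <- function(dist, atc = dist@atc, zeocin,
                              zeoParams = zeocinToxicity(),
                              atcParams = atcToxicity(), g0 = atcParams@g0,
                              threshold = defaultThreshold()) {
  stopifnot(is(dist, "FluorescenceDistribution"))
  fc <- binCenters(dist)
  hi <- fc >= threshold
  nH <- sum(dist@counts[hi])
  nL <- sum(dist@counts[!hi])
  fracHigh <- nH / (nH + nL)
  meanLow <- if (nL > 0) sum(fc[!hi] * dist@counts[!hi]) / nL else NA_real_
  meanHigh <- if (nH > 0) sum(fc[hi] * dist@counts[hi]) / nH else NA_real_
  gAt <- function(F) if (is.na(F)) 0 else
    g0 * gammaJoint(F, atc, zeocin, zeoParams, atcParams)
  if (nH == 0) {
    params <- twoStateParams(r = 0, f = 0, gL = gAt(meanLow), gH = 0)
    return(list(params = params, fractionHigh = 0, meanLow = meanLow,
                meanHigh = meanHigh, memory = NULL, singleState = TRUE))
  }
  d0 <- dist
  d0@atc <- atc
  mem <- estimateMemory(d0, threshold, atcParams, g0)
  rates <- ratesFromMemory(mem@tauL, mem@tauH, gL = gAt(meanLow),
                           gH = gAt(meanHigh))
  list(params = rates, fractionHigh = fracHigh, meanLow = meanLow,
       meanHigh = meanHigh, memory = mem, singleState = FALSE)
}

#' Predict the overall-fitness surface over (ATc, Zeocin)
#'
#' Two prediction modes from the same Zeocin-free inputs:
#' \describe{
#'   \item{fast_switching}{the distribution-weighted average
#'     \eqn{g_T = g_0 \sum \gamma_1 \gamma_2 p(F)} per condition (the
#'     stationary distribution is assumed to survive selection).}
#'   \item{memory_aware}{per condition, a two-state model is calibrated
#'     from the distribution and its cellular memories
#'     ([calibrateTwoState()]) and the dominant eigenvalue returned;
#'     selection acts through the state division rates while the switching
#'     structure is fixed by the antibiotic-free memories.}
#' }
#' ATc grid points without a supplied distribution are handled by log-linear
#' interpolation of the memory curves and linear interpolation of the
#' subpopulation structure (with a warning); the fast mode requires every
#' grid point to have a distribution.
#'
#' @param dists list of Zeocin-free [FluorescenceDistribution-class].
#' @param atcLevels ATc of each distribution, ng/ml.
#' @param atcGrid,zeocinGrid prediction grids (default: the measured ATc
#'   levels, and Zeocin \code{seq(0, 4, 0.25)}).
#' @param mode "fast_switching" or "memory_aware".
#' @param zeoParams,atcParams,g0,threshold model parameters.
#' @return A [FitnessSurface-class].
#' @export
predictSurface <- function(dists, atcLevels = NULL,
                           atcGrid = NULL, zeocinGrid = seq(0, 4, 0.25),
                           mode = c("memory_aware", "fast_switching"),
                           zeoParams = zeocinToxicity(),
                           atcParams = atcToxicity(), g0 = atcParams@g0,
                           threshold = defaultThreshold()) {
  mode <- match.arg(mode)
  if (is.null(atcLevels))
    atcLevels <- vapply(dists, function(d) d@atc, numeric(1))
  stopifnot(length(dists) == length(atcLevels))
  if (is.null(atcGrid)) atcGrid <- sort(atcLevels)
  ord <- order(atcLevels)
  atcLevels <- atcLevels[ord]; dists <- dists[ord]
  vals <- matrix(NA_real_, length(atcGrid), length(zeocinGrid))
  if (mode == "fast_switching") {
    if (!all(atcGrid %in% atcLevels))
      stop("fast_switching mode needs a distribution at every ATc grid point")
    for (i in seq_along(atcGrid)) {
      d <- dists[[match(atcGrid[i], atcLevels)]]
      vals[i, ] <- vapply(zeocinGrid, function(z)
        overallFitness(d, atc = atcGrid[i], zeocin = z, zeoParams,
                       atcParams, g0), numeric(1))
    }
  } else {
    cal <- lapply(seq_along(atcLevels), function(i)
      calibrateTwoState(dists[[i]], atc = atcLevels[i], zeocin = 0,
                        zeoParams, atcParams, g0, threshold))
    for (i in seq_along(atcGrid)) {
      C <- atcGrid[i]
      j <- match(C, atcLevels)
      if (is.na(j)) {
        warning("interpolating memory curves at ATc = ", C, " ng/ml")
        st <- interpolateCalibration(cal, atcLevels, C)
      } else {
        ci <- cal[[j]]
        st <- list(tauL = if (ci$singleState) Inf else ci$memory@tauL,
                   tauH = if (ci$singleState) Inf else ci$memory@tauH,
                   meanLow = ci$meanLow, meanHigh = ci$meanHigh,
                   singleState = ci$singleState)
      }
      for (k in seq_along(zeocinGrid)) {
        Z <- zeocinGrid[k]
        gL <- g0 * gammaJoint(st$meanLow, C, Z, zeoParams, atcParams)
        if (st$singleState) {
          vals[i, k] <- gL
        } else {
          gH <- g0 * gammaJoint(st$meanHigh, C, Z, zeoParams, atcParams)
          vals[i, k] <- populationFitness(
            ratesFromMemory(st$tauL, st$tauH, gL = gL, gH = gH))
        }
      }
    }
  }
  new("FitnessSurface", atc = sort(atcGrid), zeocin = sort(zeocinGrid),
      values = vals[order(atcGrid), order(zeocinGrid), drop = FALSE],
      mode = mode)
}

# log-linear interpolation of memories, linear for subpopulation means
interpolateCalibration <- function(cal, atcLevels, C) {
  ok <- !vapply(cal, `[[`, logical(1), "singleState")
  if (sum(ok) < 2)
    stop("cannot interpolate memory: fewer than two bimodal conditions")
  xs <- atcLevels[ok]
  tl <- vapply(cal[ok], function(ci) ci$memory@tauL, numeric(1))
  th <- vapply(cal[ok], function(ci) ci$memory@tauH, numeric(1))
  ml <- vapply(cal[ok], `[[`, numeric(1), "meanLow")
  mh <- vapply(cal[ok], `[[`, numeric(1), "meanHigh")
  list(tauL = exp(stats::approx(xs, log(tl), C, rule = 2)$y),
       tauH = exp(stats::approx(xs, log(th), C, rule = 2)$y),
       meanLow = stats::approx(xs, ml, C, rule = 2)$y,
       meanHigh = stats::approx(xs, mh, C, rule = 2)$y,
       singleState = FALSE)
}

#' Locate the drug-resistance sweet spot on a fitness surface
#'
#' The sweet spot is the inducer level maximizing predicted fitness at a
#' fixed antibiotic concentration; its sharpness is the negative discrete
#' second difference of fitness along the inducer axis at the optimum.
#'
#' @param surface a [FitnessSurface-class].
#' @param zeocinSlice antibiotic level, mg/ml (must lie on the grid).
#' @return A [SweetSpot-class]; boundary optima and flat slices are flagged.
#' @export
findSweetSpot <- function(surface, zeocinSlice) {
  stopifnot(is(surface, "FitnessSurface"))
  k <- match(zeocinSlice, surface@zeocin)
  if (is.na(k)) stop("zeocinSlice must lie on the surface grid")
  g <- surface@values[, k]
  C <- surface@atc
  flat <- diff(range(g)) < 1e-12
  i <- which.max(g)
  boundary <- i == 1L || i == length(g)
  sharp <- if (boundary || length(g) < 3) NA_real_ else {
    dC <- mean(diff(C[(i - 1):(i + 1)]))
    -(g[i - 1] - 2 * g[i] + g[i + 1]) / dC^2
  }
  new("SweetSpot", atc = C[i], zeocin = zeocinSlice, g = g[i],
      sharpness = sharp, boundary = boundary, flat = flat)
}

#' Compare memory-aware and fast-switching predictions against observations
#'
#' @param surfaceMem,surfaceFast [FitnessSurface-class] objects on a common
#'   ATc grid.
#' @param observed observed overall fitness per ATc level at the slice.
#' @param zeocinSlice antibiotic level of the observations, mg/ml.
#' @return Named vector \code{c(r2Mem = ..., r2Fast = ...)}.
#' @export
compareModels <- function(surfaceMem, surfaceFast, observed, zeocinSlice) {
  stopifnot(identical(surfaceMem@atc, surfaceFast@atc),
            length(observed) == length(surfaceMem@atc))
  kM <- match(zeocinSlice, surfaceMem@zeocin)
  kF <- match(zeocinSlice, surfaceFast@zeocin)
  if (is.na(kM) || is.na(kF)) stop("zeocinSlice must lie on both grids")
  c(r2Mem = rSquared(surfaceMem@values[, kM], observed),
    r2Fast = rSquared(surfaceFast@values[, kF], observed))
}

#' Selection-driven reshaping of the subpopulation structure
#'
#' Evolves the two-state composition under a condition for a given duration
#' (exact matrix exponential) and reports the high-expressor fraction before
#' and after, and its fold change. At the sweet spot this captures a
#' population changing from almost all low expressors to almost all high
#' expressors under selection.
#'
#' @param fractionHighBefore initial high-expressor fraction.
#' @param params a [TwoStateParams-class] at the selective condition.
#' @param duration hours.
#' @return List with \code{before}, \code{after}, \code{foldChange}.
#' @export
selectionReshaping <- function(fractionHighBefore, params, duration) {
  stopifnot(fractionHighBefore >= 0, fractionHighBefore <= 1, duration > 0)
  N <- propagateTwoState(params, c(1 - fractionHighBefore,
                                   fractionHighBefore), duration)
  after <- N[, "H"] / (N[, "L"] + N[, "H"])
  list(before = fractionHighBefore, after = unname(after),
       foldChange = unname(after) / fractionHighBefore)
}

#' Calibrated synthetic benchmark: predictions vs exact stochastic truth
#'
#' End-to-end benchmark of the landscape predictors on the calibrated
#' reference circuit. For each inducer level, stationary Zeocin-free events
#' are generated, a two-state model is calibrated from the resulting
#' distribution (memories via cellular currents, division rates via the
#' toxicity model at the benchmark antibiotic level), and overall fitness
#' under antibiotic is (a) predicted by the memory-aware eigenvalue and the
#' fast-switching average, and (b) measured by exact Gillespie simulation of
#' the same birth-switch system with periodic dilution, taking the
#' log-population slope over the last \code{lastN} samples.
#'
#' @param seed integer seed driving all randomness.
#' @param atcLevels inducer grid, ng/ml.
#' @param zeocin antibiotic level, mg/ml.
#' @param nEvents events per stationary distribution.
#' @param n0 initial (and dilution-target) population size.
#' @param duration,recordInterval simulated exposure, hours.
#' @param lastN samples entering the fitness slope.
#' @param zeoParams,atcParams,g0,threshold model parameters.
#' @return List with \code{table} (per-condition data frame: atc, predMem,
#'   predFast, simulated), \code{r2Mem}, \code{r2Fast}.
#' @export
memoryBenchmark <- function(seed = 1L, atcLevels = seq(0, 20, 2), zeocin = 2,
                            nEvents = 1e5, n0 = 1e4, duration = 72,
                            recordInterval = 12, lastN = 6,
                            zeoParams = zeocinToxicity(),
                            atcParams = atcToxicity(), g0 = atcParams@g0,
                            threshold = defaultThreshold()) {
  predMem <- predFast <- sim <- numeric(length(atcLevels))
  for (i in seq_along(atcLevels)) {
    C <- atcLevels[i]
    ev <- generateStationaryEvents(circuitMixtureSpec(C, nEvents),
                                   seed = seed + 1000L * i, atc = C)
    dist <- buildHistogram(ev)
    cal <- calibrateTwoState(dist, atc = C, zeocin = zeocin, zeoParams,
                             atcParams, g0, threshold)
    predMem[i] <- if (cal$singleState) cal$params@gL
                  else populationFitness(cal$params)
    predFast[i] <- overallFitness(dist, atc = C, zeocin = zeocin, zeoParams,
                                  atcParams, g0)
    nH0 <- round(n0 * cal$fractionHigh)
    traj <- simulateBirthSwitch(cal$params, n0L = n0 - nH0, n0H = nH0,
                                config = simConfig(duration = duration,
                                                   recordInterval =
                                                     recordInterval,
                                                   seed = seed + 1000L * i +
                                                     500L),
                                dilutionTarget = n0)
    ln <- logPopulation(traj)
    tt <- traj@times
    keep <- seq.int(max(1L, length(tt) - lastN + 1L), length(tt))
    sim[i] <- unname(stats::coef(stats::lm(ln[keep] ~ tt[keep]))[2])
  }
  list(table = data.frame(atc = atcLevels, predMem = predMem,
                          predFast = predFast, simulated = sim),
       r2Mem = rSquared(predMem, sim), r2Fast = rSquared(predFast, sim))
}
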