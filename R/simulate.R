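# Synthetic-data generators: every downstream stage of the pipeline can be
# exercised against data with known ground truth.

#' Exact stochastic simulation of the birth-switch population process
#'
#' Event-driven (Gillespie) realization of the two-state population model:
#' low-state cells divide at \code{gL} and rise at \code{r}; high-state cells
#' divide at \code{gH} and fall at \code{f}. The expectation of the process
#' obeys the two-state ODE system, and the long-run slope of the log
#' population equals the dominant eigenvalue.
#'
#' With \code{dilutionTarget} set, the population is subsampled binomially
#' back to that size at every record time, emulating the periodic
#' resuspension used to keep cultures in exponential growth; the cumulative
#' log dilution factor is retained so [logPopulation()] still reports the
#' undiluted log population size.
#'
#' @param params a [TwoStateParams-class] (all rates non-negative).
#' @param n0L,n0H initial cell counts (n0L + n0H >= 1).
#' @param config a [SimConfig-class]; its seed drives the RNG.
#' @param dilutionTarget optional population size to dilute back to at each
#'   record time (NULL = no dilution).
#' @return A [PopulationTrajectory-class]. Extinction is flagged and the
#'   trajectory truncated at the extinction record.
#' @examples
#' p <- twoStateParams(r = 0.02, f = 0.01, gL = 0.1, gH = 0.1)
#' traj <- simulateBirthSwitch(p, 500, 500, simConfig(duration = 48, seed = 1))
#' @export
simulateBirthSwitch <- function(params, n0L, n0H, config,
                                dilutionTarget = NULL) {
  stopifnot(is(params, "TwoStateParams"), is(config, "SimConfig"))
  if (params@r < 0 || params@f < 0 || params@gL < 0 || params@gH < 0)
    stop("all rates must be non-negative")
  if (n0L + n0H < 1) stop("need at least one initial cell")
  res <- withSeed(config@seed,
    birth_switch_gillespie(params@gL, params@gH, params@r, params@f,
                           round(n0L), round(n0H), config@duration,
                           config@recordInterval,
                           if (is.null(dilutionTarget)) 0 else dilutionTarget))
  keep <- seq_along(res$times)
  if (res$extinct) {
    warning("population went extinct; trajectory truncated")
    dead <- which(res$nL + res$nH <= 0)
    if (length(dead)) keep <- seq_len(min(dead))
  }
  new("PopulationTrajectory", times = res$times[keep], nL = res$nL[keep],
      nH = res$nH[keep], logDilution = res$logDilution[keep],
      extinct = res$extinct)
}

#' Simulate a single-cell lineage of the switching process
#'
#' A lineage switches L -> H at rate \code{r} and H -> L at rate \code{f};
#' holding times are exponential with means 1/r and 1/f. Division rates play
#' no role in the lineage perspective (no fitness weighting).
#'
#' @param params a [TwoStateParams-class]; only r and f are used.
#' @param config a [SimConfig-class] (duration, seed).
#' @param startState initial state, "L" or "H"; by default drawn from the
#'   stationary occupancy r/(r+f).
#' @return A [LineageTrace-class]; degenerate (single-state) with a warning
#'   when r = f = 0.
#' @export
simulateLineage <- function(params, config, startState = NULL) {
  stopifnot(is(params, "TwoStateParams"), is(config, "SimConfig"))
  r <- params@r; f <- params@f
  if (r < 0 || f < 0) stop("rates must be non-negative")
  withSeed(config@seed, {
    if (is.null(startState)) {
      pH <- if (r + f > 0) r / (r + f) else 0.5
      startState <- if (stats::runif(1) < pH) "H" else "L"
    }
    if (r == 0 && f == 0) {
      warning("r = f = 0: degenerate single-state lineage")
      return(new("LineageTrace", switchTimes = numeric(0),
                 states = startState, duration = config@duration,
                 degenerate = TRUE))
    }
    # draw alternating exponential sojourns in blocks until the horizon
    switchTimes <- numeric(0)
    states <- startState
    state <- startState
    t <- 0
    repeat {
      rate <- if (state == "L") r else f
      if (rate == 0) break  # absorbed in this state
      other <- if (state == "L") f else r
      if (other == 0) {  # one switch then absorbed
        t <- t + stats::rexp(1, rate)
        if (t < config@duration) {
          switchTimes <- c(switchTimes, t)
          state <- if (state == "L") "H" else "L"
          states <- c(states, state)
        }
        break
      }
      meanCycle <- 1 / rate + 1 / other
      nBlock <- max(16L, ceiling(2 * (config@duration - t) / meanCycle))
      rates <- rep_len(if (state == "L") c(r, f) else c(f, r), 2L * nBlock)
      tims <- t + cumsum(stats::rexp(length(rates), rates))
      keep <- tims < config@duration
      newStates <- rep_len(if (state == "L") c("H", "L") else c("L", "H"),
                           length(rates))[keep]
      switchTimes <- c(switchTimes, tims[keep])
      states <- c(states, newStates)
      if (any(!keep)) break
      t <- tims[length(tims)]
      state <- states[length(states)]
    }
    new("LineageTrace", switchTimes = switchTimes, states = states,
        duration = config@duration, degenerate = FALSE)
  })
}

#' Fraction of time a lineage trace spends in the high state
#'
#' @param trace a [LineageTrace-class].
#' @return Occupancy of state "H" in [0, 1].
#' @export
occupancyHigh <- function(trace) {
  stopifnot(is(trace, "LineageTrace"))
  bounds <- c(0, trace@switchTimes, trace@duration)
  sum(diff(bounds)[trace@states == "H"]) / trace@duration
}

#' Mean holding times per state observed in a lineage trace
#'
#' Only completed sojourns (bounded by switches on both sides) are counted.
#'
#' @param trace a [LineageTrace-class].
#' @return Named vector \code{c(L = ..., H = ...)} of mean sojourn times (h);
#'   NA where no completed sojourn exists.
#' @export
meanHoldingTimes <- function(trace) {
  bounds <- c(0, trace@switchTimes, trace@duration)
  durs <- diff(bounds)
  n <- length(durs)
  complete <- if (n > 2L) 2:(n - 1L) else integer(0)
  st <- trace@states[complete]
  c(L = if (any(st == "L")) mean(durs[complete][st == "L"]) else NA_real_,
    H = if (any(st == "H")) mean(durs[complete][st == "H"]) else NA_real_)
}

#' Draw a stationary single-cell event table from a mixture specification
#'
#' Fluorescence is drawn from the two-component log-normal mixture (log10
#' scale); forward and side scatter are correlated log-normals driven by a
#' shared latent cell-size factor. Bit-reproducible for a given seed.
#'
#' @param spec a [MixtureSpec-class].
#' @param seed integer RNG seed.
#' @param atc,zeocin condition annotation for the table.
#' @return An [EventTable-class].
#' @export
generateStationaryEvents <- function(spec, seed, atc = 0, zeocin = 0) {
  stopifnot(is(spec, "MixtureSpec"))
  withSeed(seed, {
    n <- spec@nEvents
    isHigh <- stats::runif(n) < spec@fractionHigh
    logF <- ifelse(isHigh,
                   stats::rnorm(n, log10(spec@highMode), spec@logSdHigh),
                   stats::rnorm(n, log10(spec@lowMode), spec@logSdLow))
    size <- stats::rnorm(n)  # shared latent size factor
    fsc <- 10^(spec@scatterLocation + spec@scatterScale *
                 (0.8 * size + 0.6 * stats::rnorm(n)))
    ssc <- 10^(spec@scatterLocation - 0.15 + spec@scatterScale *
                 (0.8 * size + 0.6 * stats::rnorm(n)))
    eventTable(fl1 = 10^logF, fsc = fsc, ssc = ssc, atc = atc,
               zeocin = zeocin)
  })
}

#' Generate an exponential growth curve with multiplicative count noise
#'
#' Counts follow N0 * exp(g * t) * eps_t with eps_t log-normal of coefficient
#' of variation \code{config@noiseCv}, sampled every
#' \code{config@recordInterval} hours.
#'
#' @param gTrue growth rate, per hour.
#' @param n0 initial density, cells/ml (> 0).
#' @param config a [SimConfig-class].
#' @param atc,zeocin condition annotation.
#' @return A [GrowthCurve-class].
#' @export
generateGrowthCurve <- function(gTrue, n0, config, atc = 0, zeocin = 0) {
  stopifnot(is(config, "SimConfig"), n0 > 0)
  withSeed(config@seed, {
    times <- seq(0, config@duration, by = config@recordInterval)
    mu <- n0 * exp(gTrue * times)
    if (config@noiseCv > 0) {
      sdlog <- sqrt(log(1 + config@noiseCv^2))
      mu <- mu * stats::rlnorm(length(times), -sdlog^2 / 2, sdlog)
    }
    growthCurve(times, mu, atc = atc, zeocin = zeocin)
  })
}

#' Generate a synthetic sorting-relaxation experiment
#'
#' Three subpopulation-ratio time courses (high-sorted, low-sorted, unsorted)
#' are produced from the analytic solution of the two-state population model,
#' with multiplicative log-normal measurement noise on the ratios. The sorted
#' arms start from the sort purity; the unsorted arm starts from (and stays
#' near) the stationary composition.
#'
#' @param params a [TwoStateParams-class] (generating truth).
#' @param purity sort purity, in (0.5, 1].
#' @param config a [SimConfig-class]; duration, recordInterval, noiseCv, seed.
#' @return A [SortRelaxationData-class].
#' @export
generateSortingExperiment <- function(params, purity = 0.99, config) {
  stopifnot(is(params, "TwoStateParams"), is(config, "SimConfig"))
  if (purity <= 0.5 || purity > 1) stop("purity must lie in (0.5, 1]")
  times <- seq(0, config@duration, by = config@recordInterval)
  xStat <- stationaryComposition(params)
  arms <- list(
    highSorted = ratioTrajectory(params, n0L = 1 - purity, n0H = purity,
                                 times = times),
    lowSorted = ratioTrajectory(params, n0L = purity, n0H = 1 - purity,
                                times = times),
    unsorted = ratioTrajectory(params, n0L = xStat["L"], n0H = xStat["H"],
                               times = times))
  withSeed(config@seed, {
    if (config@noiseCv > 0) {
      sdlog <- sqrt(log(1 + config@noiseCv^2))
      arms <- lapply(arms, function(R)
        R * stats::rlnorm(length(R), -sdlog^2 / 2, sdlog))
    }
    new("SortRelaxationData", times = times, highSorted = arms$highSorted,
        lowSorted = arms$lowSorted, unsorted = arms$unsorted)
  })
}

#' Simulate single-cell fluorescence lineages with pure-dilution decay
#'
#' Microscopic oracle for the cellular-current memory estimator. Each cell
#' carries a telegraph production state switching L -> H at rate \code{r} and
#' H -> L at rate \code{f} (rates from \code{params}). On switching up,
#' fluorescence jumps to a draw from the high mode (activation is fast
#' relative to dilution); while production is off, fluorescence decays by
#' growth dilution toward a basal level drawn from the low mode:
#' F(t) = B + (F0 - B) exp(-g t). Downward threshold crossings and residence
#' times above the threshold are recorded exactly, and snapshot events are
#' collected at the requested times.
#'
#' @param params a [TwoStateParams-class]; only r and f are used.
#' @param gDilution dilution (growth) rate, per hour.
#' @param spec a [MixtureSpec-class] giving the two modes (fractionHigh is
#'   ignored; occupancy follows from r and f).
#' @param nCells number of independent cells.
#' @param duration simulated hours per cell; snapshots are taken at
#'   \code{sampleTimes} (after burn-in).
#' @param sampleTimes snapshot times, hours.
#' @param threshold fluorescence threshold for crossing statistics, a.u.
#' @param seed RNG seed.
#' @return List with \code{events} (snapshot [EventTable-class]),
#'   \code{downCrossingsPerHour} (mean downward crossings per cell-hour),
#'   \code{meanResidenceHigh}, \code{meanResidenceLow} (hours, completed
#'   residences above/below the threshold), and \code{occupancyHigh}.
#' @export
simulateDilutionLineages <- function(params, gDilution, spec, nCells = 1000,
                                     duration = 400,
                                     sampleTimes = seq(100, duration, by = 20),
                                     threshold = defaultThreshold(),
                                     seed = 1L) {
  stopifnot(is(params, "TwoStateParams"), is(spec, "MixtureSpec"),
            gDilution > 0, all(sampleTimes <= duration))
  r <- params@r; f <- params@f
  if (r <= 0 || f <= 0) stop("need strictly positive switching rates")
  withSeed(seed, {
    snapF <- matrix(NA_real_, nCells, length(sampleTimes))
    nDown <- 0
    resHigh <- c(); resLow <- c()
    drawHigh <- function(k) 10^stats::rnorm(k, log10(spec@highMode),
                                            spec@logSdHigh)
    drawLow <- function(k) 10^stats::rnorm(k, log10(spec@lowMode),
                                           spec@logSdLow)
    pH <- r / (r + f)
    for (cell in seq_len(nCells)) {
      state <- stats::runif(1) < pH  # TRUE = production on (high)
      Fcur <- if (state) drawHigh(1) else drawLow(1)
      base <- drawLow(1)
      t <- 0
      lastUp <- if (Fcur >= threshold) 0 else NA_real_
      lastDown <- if (Fcur < threshold) 0 else NA_real_
      while (t < duration) {
        soj <- stats::rexp(1, if (state) f else r)
        tEnd <- min(t + soj, duration)
        if (state) {
          # production on: fluorescence holds at its high-mode draw
          sel <- sampleTimes > t & sampleTimes <= tEnd
          snapF[cell, sel] <- Fcur
        } else {
          # production off: dilution decay toward the basal level
          sel <- which(sampleTimes > t & sampleTimes <= tEnd)
          if (length(sel))
            snapF[cell, sel] <- base +
              (Fcur - base) * exp(-gDilution * (sampleTimes[sel] - t))
          if (Fcur >= threshold && base < threshold) {
            tc <- log((Fcur - base) / (threshold - base)) / gDilution
            if (t + tc <= tEnd) {
              nDown <- nDown + 1
              if (!is.na(lastUp)) resHigh <- c(resHigh, t + tc - lastUp)
              lastDown <- t + tc
              lastUp <- NA_real_
            }
          }
          Fcur <- base + (Fcur - base) * exp(-gDilution * (tEnd - t))
        }
        t <- tEnd
        if (t >= duration) break
        if (state) {
          # switch off: decay starts from current high value
          state <- FALSE
          base <- drawLow(1)
        } else {
          # switch on: fast activation, jump into the high mode
          state <- TRUE
          newF <- drawHigh(1)
          if (Fcur < threshold && newF >= threshold) {
            if (!is.na(lastDown)) resLow <- c(resLow, t - lastDown)
            lastUp <- t
            lastDown <- NA_real_
          }
          Fcur <- newF
        }
      }
    }
    fl <- as.vector(snapF)
    fl <- fl[!is.na(fl)]
    list(events = eventTable(fl1 = fl),
         downCrossingsPerHour = nDown / (nCells * duration),
         meanResidenceHigh = if (length(resHigh)) mean(resHigh) else NA_real_,
         meanResidenceLow = if (length(resLow)) mean(resLow) else NA_real_,
         occupancyHigh = mean(fl >= threshold))
  })
}
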