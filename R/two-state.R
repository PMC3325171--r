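# The two-state switching population model: spectral solution, eigenvalue
# fitness, switching-rate fitting from sorting-relaxation data, lineage
# occupancy, and fluctuating-environment simulation.

twoStateMatrix <- function(params)
  matrix(c(params@gL - params@r, params@r,
           params@f, params@gH - params@f), 2, 2,
         dimnames = list(c("L", "H"), NULL))

#' Spectral solution of the two-state population model
#'
#' Closed-form eigen-decomposition of the rate matrix
#' \code{[[gL - r, f], [r, gH - f]]}:
#' \deqn{a_{1,2} = \tfrac12\left[(g_L - r + g_H - f) \pm
#'   \sqrt{(g_L - r - g_H + f)^2 + 4 r f}\right].}
#' The dominant eigenvalue a1 is always real.
#'
#' @param params a [TwoStateParams-class].
#' @return A [SpectralSolution-class].
#' @export
solveTwoState <- function(params) {
  stopifnot(is(params, "TwoStateParams"))
  aL <- params@gL - params@r
  aH <- params@gH - params@f
  disc <- sqrt((aL - aH)^2 + 4 * params@r * params@f)
  a1 <- (aL + aH + disc) / 2
  a2 <- (aL + aH - disc) / 2
  vec <- function(a) {
    # (A - a I) v = 0; pick the numerically stable component pair
    if (params@f > 0) v <- c(params@f, a - aL)
    else if (params@r > 0) v <- c(a - aH, params@r)
    else v <- if (abs(a - aL) < abs(a - aH)) c(1, 0) else c(0, 1)
    nv <- sqrt(sum(v^2))
    if (nv == 0) c(1, 0) else v / nv
  }
  new("SpectralSolution", a1 = a1, a2 = a2,
      vectors = cbind(vec(a1), vec(a2)), params = params)
}

#' Asymptotic population fitness of the two-state model
#'
#' The overall cell division rate after long times is the dominant
#' eigenvalue a1 of the two-state rate matrix.
#'
#' @param params a [TwoStateParams-class].
#' @return Fitness, per hour.
#' @export
populationFitness <- function(params) solveTwoState(params)@a1

#' Propagate the two-state populations forward in time
#'
#' Exact matrix-exponential solution N(t) = exp(A t) N(0), computed from the
#' closed-form spectral decomposition (with the defective r = f = 0,
#' gL = gH case handled by the diagonal limit).
#'
#' @param params a [TwoStateParams-class].
#' @param n0 initial counts \code{c(L, H)}.
#' @param times times at which to evaluate, hours.
#' @return Matrix with columns \code{L}, \code{H}, one row per time.
#' @export
propagateTwoState <- function(params, n0, times) {
  stopifnot(length(n0) == 2)
  sol <- solveTwoState(params)
  A <- twoStateMatrix(params)
  if (abs(sol@a1 - sol@a2) < 1e-12 * max(1, abs(sol@a1))) {
    # repeated eigenvalue: exp(At) = e^{a t}(I + (A - aI) t)
    out <- t(vapply(times, function(t)
      exp(sol@a1 * t) * as.numeric((diag(2) + (A - sol@a1 * diag(2)) * t)
                                   %*% n0),
      numeric(2)))
  } else {
    V <- sol@vectors
    cc <- solve(V, n0)
    out <- t(vapply(times, function(t)
      as.numeric(V %*% (cc * exp(c(sol@a1, sol@a2) * t))), numeric(2)))
  }
  out[times == 0, ] <- rep(n0, each = sum(times == 0))  # exact at t = 0
  colnames(out) <- c("L", "H")
  out
}

#' Closed-form subpopulation ratio trajectory R(t) = N_L(t) / N_H(t)
#'
#' @param params a [TwoStateParams-class].
#' @param n0L,n0H initial counts (any positive scale).
#' @param times hours.
#' @return Ratio at each time.
#' @export
ratioTrajectory <- function(params, n0L, n0H, times) {
  sol <- solveTwoState(params)
  if (abs(sol@a1 - sol@a2) < 1e-12 * max(1, abs(sol@a1))) {
    N <- propagateTwoState(params, c(n0L, n0H), times)
    return(N[, "L"] / N[, "H"])
  }
  # scale out exp(a1 t): the ratio depends only on the spectral gap, so it
  # stays finite for arbitrarily long horizons
  V <- sol@vectors
  cc <- solve(V, c(n0L, n0H))
  w <- exp((sol@a2 - sol@a1) * times)
  out <- (cc[1] * V[1, 1] + cc[2] * w * V[1, 2]) /
         (cc[1] * V[2, 1] + cc[2] * w * V[2, 2])
  out[times == 0] <- n0L / n0H
  out
}

#' Stationary composition of the two-state model
#'
#' Fractions of low and high cells in the dominant eigenvector (the
#' composition the population relaxes to).
#'
#' @param params a [TwoStateParams-class].
#' @return Named vector \code{c(L = ..., H = ...)} summing to 1.
#' @export
stationaryComposition <- function(params) {
  v <- solveTwoState(params)@vectors[, 1]
  v <- abs(v)
  v <- v / sum(v)
  c(L = v[1], H = v[2])
}

#' Fit switching rates to sorting-relaxation data
#'
#' The log-transformed ratio ln R(t) of the two-state analytic solution is
#' fit jointly to the normalized log-ratios of the high-sorted and
#' low-sorted arms by Nelder-Mead least squares over (log r, log f). Each
#' sorted log-ratio is normalized by dividing by the unsorted log-ratio at
#' the same time point and multiplying by the mean unsorted log-ratio over
#' all time points (drift correction; the unsorted arm itself is not fit).
#' Initial compositions per arm are taken from the arm's first observed
#' ratio. Confidence intervals by case-resampling bootstrap over time points.
#'
#' @param data a [SortRelaxationData-class] with >= 4 time points.
#' @param gL,gH state division rates, per hour, held fixed during the fit.
#' @param nBoot bootstrap draws for 95 percent CIs (0 = skip).
#' @param seed RNG seed for the bootstrap.
#' @return List with \code{params} ([TwoStateParams-class]), \code{ci}
#'   (2x2 matrix of 95 percent CIs for r and f, or NULL), and \code{value}
#'   (residual sum of squares).
#' @export
fitSwitchingRates <- function(data, gL, gH, nBoot = 1000, seed = 1L) {
  stopifnot(is(data, "SortRelaxationData"))
  if (length(data@times) < 4) stop("need at least 4 time points per arm")
  r0High <- data@highSorted[1]
  r0Low <- data@lowSorted[1]
  tt <- data@times
  lnUns <- log(data@unsorted)
  norm <- mean(lnUns[is.finite(lnUns)])
  lnHigh <- log(data@highSorted) / lnUns * norm
  lnLow <- log(data@lowSorted) / lnUns * norm
  ok <- is.finite(lnHigh) & is.finite(lnLow)
  tt <- tt[ok]; lnHigh <- lnHigh[ok]; lnLow <- lnLow[ok]
  if (r0High <= 0) r0High <- 1e-12
  if (r0Low <= 0) r0Low <- 1e-12
  if (!is.finite(r0High)) r0High <- 1e12
  if (!is.finite(r0Low)) r0Low <- 1e12
  fitOnce <- function(idx, warmStart = NULL) {
    obj <- function(lp) {
      p <- exp(lp)
      par <- twoStateParams(r = p[1], f = p[2], gL = gL, gH = gH)
      mh <- log(ratioTrajectory(par, r0High, 1, tt[idx]))
      ml <- log(ratioTrajectory(par, r0Low, 1, tt[idx]))
      sum((mh - lnHigh[idx])^2) + sum((ml - lnLow[idx])^2)
    }
    starts <- if (is.null(warmStart))
      lapply(asplit(expand.grid(r = c(1e-3, 3e-2), f = c(1e-4, 3e-3)), 1),
             function(s) log(as.numeric(s)))
    else list(warmStart)
    best <- NULL
    for (s0 in starts) {
      opt <- stats::optim(s0, obj, method = "Nelder-Mead",
                          control = list(maxit = if (is.null(warmStart)) 800
                                                 else 500,
                                         reltol = if (is.null(warmStart))
                                           1e-12 else 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(warmStart)) {  # polish the full fit only
      opt <- stats::optim(best$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-13))
      if (opt$value <= best$value) best <- opt
    }
    if (!is.finite(best$value) || any(!is.finite(exp(best$par))))
      stop("switching-rate fit did not converge")
    c(r = exp(best$par[1]), f = exp(best$par[2]), value = best$value,
      lpar = best$par)
  }
  full <- fitOnce(seq_along(tt))
  ci <- NULL
  if (nBoot > 0) {
    warm <- unname(full[c("lpar1", "lpar2")])
    boots <- withSeed(seed, {
      vapply(seq_len(nBoot), function(b) {
        idx <- sort(sample(seq_along(tt), replace = TRUE))
        out <- tryCatch(fitOnce(idx, warmStart = warm)[1:2],
                        error = function(e) c(NA, NA))
        out
      }, numeric(2))
    })
    ci <- t(apply(boots, 1, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
    rownames(ci) <- c("r", "f")
  }
  list(params = twoStateParams(r = unname(full["r"]), f = unname(full["f"]),
                               gL = gL, gH = gH),
       ci = ci, value = unname(full["value"]))
}

#' Time-averaged lineage occupancy of the high state
#'
#' A lineage's probability of being high obeys
#' dp_H/dt = r (1 - p_H) - f p_H, whose solution from p_H(0) = p0 is
#' \deqn{p_H(t) = p_\infty + (p_0 - p_\infty) e^{-(r+f)t}, \quad
#'       p_\infty = r/(r+f).}
#' The time average over a window [0, T] follows in closed form; an infinite
#' window returns the asymptotic occupancy r/(r+f).
#'
#' @param params a [TwoStateParams-class]; only r and f are used (lineage
#'   perspective: switching only, no fitness weighting).
#' @param p0High initial probability of being in the high state.
#' @param window averaging window, hours (may be Inf).
#' @return Mean occupancy of the high state over the window.
#' @export
lineageOccupancy <- function(params, p0High = NULL, window = Inf) {
  stopifnot(is(params, "TwoStateParams"))
  k <- params@r + params@f
  if (is.infinite(window)) {
    if (k <= 0) stop("asymptotic occupancy needs r + f > 0")
    return(params@r / k)
  }
  stopifnot(!is.null(p0High), window > 0)
  if (k <= 0) return(p0High)
  pInf <- params@r / k
  pInf + (p0High - pInf) * (1 - exp(-k * window)) / (k * window)
}

#' Switching rates from cellular memories
#'
#' Memory is the inverse of the spontaneous switching rate:
#' r = 1/tau_L, f = 1/tau_H; infinite memory maps to rate zero.
#'
#' @param tauL,tauH memories, hours (> 0, may be Inf).
#' @param gL,gH optional division rates to carry along.
#' @return A [TwoStateParams-class].
#' @export
ratesFromMemory <- function(tauL, tauH, gL = 0, gH = 0) {
  stopifnot(tauL > 0, tauH > 0)
  twoStateParams(r = if (is.infinite(tauL)) 0 else 1 / tauL,
                 f = if (is.infinite(tauH)) 0 else 1 / tauH,
                 gL = gL, gH = gH)
}

#' Long-run fitness in an environment fluctuating between two conditions
#'
#' The environment alternates between a "normal" and a "toxic" condition,
#' either periodically (fixed durations) or randomly (exponential durations
#' with the given means). Within each episode the two-state populations are
#' propagated exactly (closed-form matrix exponential) in normalized
#' coordinates, accumulating log population size, so arbitrarily long
#' horizons cannot overflow. The long-run fitness is
#' ln(N(horizon)/N(0)) / horizon, averaged over realizations for random
#' schedules.
#'
#' @param paramsNormal,paramsToxic [TwoStateParams-class] for the two
#'   conditions.
#' @param schedule "periodic" or "random".
#' @param meanNormal,meanToxic mean episode durations, hours.
#' @param horizon total simulated time, hours (should span many episodes).
#' @param nRealizations realizations averaged for random schedules.
#' @param startEnv environment at time 0 ("normal" or "toxic").
#' @param seed RNG seed (random schedules).
#' @return Long-run fitness, per hour.
#' @export
simulateFluctuatingEnvironment <- function(paramsNormal, paramsToxic,
                                           schedule = c("random", "periodic"),
                                           meanNormal, meanToxic, horizon,
                                           nRealizations = 20,
                                           startEnv = "normal", seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(meanNormal >= 0, meanToxic >= 0, horizon > 0,
            meanNormal + meanToxic > 0)
  comp0 <- stationaryComposition(paramsNormal)
  oneRun <- function(random) {
    env <- startEnv
    t <- 0
    v <- c(comp0[["L"]], comp0[["H"]])
    logN <- 0
    while (t < horizon - 1e-9) {
      mu <- if (env == "normal") meanNormal else meanToxic
      dur <- if (mu <= 0) 0 else if (random) stats::rexp(1, 1 / mu) else mu
      dur <- min(dur, horizon - t)
      if (dur > 0) {
        par <- if (env == "normal") paramsNormal else paramsToxic
        N <- propagateTwoState(par, v, dur)
        tot <- sum(N)
        logN <- logN + log(tot)
        v <- as.numeric(N / tot)
      }
      t <- t + dur
      env <- if (env == "normal") "toxic" else "normal"
    }
    logN / horizon
  }
  if (schedule == "periodic") return(oneRun(FALSE))
  withSeed(seed, mean(vapply(seq_len(nRealizations), function(i)
    oneRun(TRUE), numeric(1))))
}
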