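# Flow-cytometry style processing: gating, histograms, smoothing, bimodality
# detection, threshold selection and subpopulation statistics.

#' Elliptical scatter gate
#'
#' Fits a two-dimensional Gaussian to (log SSC, log FSC) and retains the
#' events inside the elliptical contour where the fitted density is at least
#' \code{gateFraction} times its maximum. For a true 2-D Gaussian this
#' contour (Mahalanobis^2 <= -2 log(gateFraction), a chi-squared with 2 df)
#' contains a fraction 1 - gateFraction of the events, so the default 0.90
#' gate keeps the densest 10 percent of the scatter cloud.
#'
#' @param events an [EventTable-class] with at least 100 events and positive
#'   scatter values.
#' @param gateFraction density cut as a fraction of the maximum, in [0, 1).
#' @return The gated [EventTable-class]; a warning is raised if fewer than
#'   100 events survive.
#' @export
gateEvents <- function(events, gateFraction = 0.90) {
  stopifnot(is(events, "EventTable"))
  if (nEvents(events) < 100) stop("need at least 100 events to fit the gate")
  sc <- scatterChannels(events)
  if (any(sc <= 0)) stop("scatter values must be positive")
  ls <- log(sc)
  mu <- colMeans(ls)
  S <- stats::cov(ls)
  if (!is.finite(determinant(S)$modulus) || rcond(S) < 1e-12)
    stop("singular scatter covariance; cannot fit the elliptical gate")
  md2 <- stats::mahalanobis(ls, mu, S)
  keep <- md2 <= -2 * log(gateFraction)
  if (sum(keep) < 100)
    warning("fewer than 100 events inside the gate")
  new("EventTable", exprs = events@exprs[keep, , drop = FALSE],
      atc = events@atc, zeocin = events@zeocin)
}

#' Bin fluorescence events into a log-spaced histogram
#'
#' Half-open bins \code{[lo, hi)}, log-spaced. Events with non-positive
#' fluorescence, or outside the range, are dropped and counted in the
#' \code{dropped} slot.
#'
#' @param events an [EventTable-class].
#' @param nBins number of bins (default 256).
#' @param range fluorescence range covered, a.u. (default \code{c(1, 1e4)}).
#' @return A [FluorescenceDistribution-class].
#' @export
buildHistogram <- function(events, nBins = 256, range = c(1, 1e4)) {
  stopifnot(is(events, "EventTable"), length(range) == 2, range[1] > 0,
            range[2] > range[1], nBins >= 2)
  fl <- fluorescence(events)
  bad <- fl <= 0
  fl <- fl[!bad]
  breaks <- 10^seq(log10(range[1]), log10(range[2]), length.out = nBins + 1)
  idx <- findInterval(fl, breaks, rightmost.closed = FALSE)
  inRange <- idx >= 1L & idx <= nBins & fl < range[2]
  counts <- tabulate(idx[inRange], nbins = nBins)
  new("FluorescenceDistribution", breaks = breaks, counts = as.numeric(counts),
      smoothed = numeric(0), smoothWindow = 0,
      dropped = sum(bad) + sum(!inRange), massChange = 0,
      atc = events@atc, zeocin = events@zeocin)
}

#' Smooth a binned fluorescence distribution
#'
#' \code{"moving-average"} applies a centered moving average of
#' \code{window} bins (edge bins averaged over the available shrinking
#' window), the smoother used by the bimodality z-test, whose variance model
#' is expectation / window. \code{"gaussian"} applies a discrete Gaussian
#' kernel of standard deviation \code{bandwidth} bins (renormalized at the
#' edges), the gentler smoother used to fill empty bins before
#' cellular-current evaluation.
#'
#' @param dist a [FluorescenceDistribution-class].
#' @param window moving-average window, bins (default 32).
#' @param method "moving-average" or "gaussian".
#' @param bandwidth Gaussian kernel SD, bins (default 2).
#' @return The distribution with \code{smoothed} counts filled in; the exact
#'   total-mass change is recorded in \code{massChange}.
#' @export
smoothHistogram <- function(dist, window = 32,
                            method = c("moving-average", "gaussian"),
                            bandwidth = 2) {
  stopifnot(is(dist, "FluorescenceDistribution"))
  method <- match.arg(method)
  n <- length(dist@counts)
  x <- dist@counts
  if (method == "moving-average") {
    if (window < 1 || window > n)
      stop("window must lie between 1 and the number of bins")
    h1 <- floor((window - 1) / 2)
    h2 <- ceiling((window - 1) / 2)
    sm <- vapply(seq_len(n), function(i)
      mean(x[max(1, i - h1):min(n, i + h2)]), numeric(1))
    w <- window
  } else {
    half <- max(1L, ceiling(4 * bandwidth))
    k <- stats::dnorm(-half:half, sd = bandwidth)
    sm <- vapply(seq_len(n), function(i) {
      j <- max(1, i - half):min(n, i + half)
      kk <- k[j - i + half + 1]
      sum(x[j] * kk) / sum(kk)
    }, numeric(1))
    # effective averaging window of the kernel, for the variance model
    w <- 1 / sum((k / sum(k))^2)
  }
  dist@smoothed <- sm
  dist@smoothWindow <- w
  dist@massChange <- sum(sm) - sum(x)
  dist
}

#' Test a smoothed fluorescence histogram for bimodality
#'
#' Bin occupancies are near-Poisson, so a smoothed count \eqn{s} carries
#' variance \eqn{s / W} where \eqn{W} is the averaging window. Every interior
#' local minimum of the smoothed counts is compared with the largest smoothed
#' count on each side using the two-sample z statistic
#' \deqn{z = (\mu_{max} - \mu_{min}) / \sqrt{(\mu_{max} + \mu_{min}) / W}.}
#' The histogram is bimodal when some minimum scores \code{z > zCutoff}
#' against both flanking maxima.
#'
#' @param dist a smoothed [FluorescenceDistribution-class] (see
#'   [smoothHistogram()]).
#' @param zCutoff z threshold (default 4).
#' @return A [BimodalityResult-class]; with fewer than three extrema the
#'   result is simply "not bimodal".
#' @export
bimodalityTest <- function(dist, zCutoff = 4) {
  stopifnot(is(dist, "FluorescenceDistribution"))
  if (!length(dist@smoothed))
    stop("smooth the histogram first (smoothHistogram)")
  s <- dist@smoothed
  W <- dist@smoothWindow
  ext <- localExtrema(s)
  centers <- binCenters(dist)
  notBimodal <- new("BimodalityResult", isBimodal = FALSE,
                    candidates = numeric(0), zLeft = numeric(0),
                    zRight = numeric(0), threshold = NA_real_)
  if (length(ext$maxima) < 2L || length(ext$minima) < 1L) return(notBimodal)
  cand <- zL <- zR <- numeric(0)
  zstat <- function(hi, lo) (hi - lo) / sqrt((hi + lo) / W)
  for (m in ext$minima) {
    leftMax <- ext$maxima[ext$maxima < m]
    rightMax <- ext$maxima[ext$maxima > m]
    if (!length(leftMax) || !length(rightMax)) next
    muL <- max(s[leftMax])
    muR <- max(s[rightMax])
    z1 <- zstat(muL, s[m])
    z2 <- zstat(muR, s[m])
    if (is.finite(z1) && is.finite(z2) && z1 > zCutoff && z2 > zCutoff) {
      cand <- c(cand, centers[m]); zL <- c(zL, z1); zR <- c(zR, z2)
    }
  }
  if (!length(cand)) return(notBimodal)
  res <- new("BimodalityResult", isBimodal = TRUE, candidates = cand,
             zLeft = zL, zRight = zR, threshold = NA_real_)
  res@threshold <- selectThreshold(res)
  res
}

#' Select the classification threshold from a bimodality result
#'
#' Among the accepted valley candidates, returns the one maximizing the
#' product of its two z-scores; ties break toward lower fluorescence.
#'
#' @param result a [BimodalityResult-class] with \code{isBimodal = TRUE}.
#' @return Threshold fluorescence, a.u.
#' @export
selectThreshold <- function(result) {
  stopifnot(is(result, "BimodalityResult"))
  if (!result@isBimodal)
    stop("distribution is not bimodal; fall back to the constant threshold ",
         "(defaultThreshold())")
  zprod <- result@zLeft * result@zRight
  best <- which(zprod == max(zprod))
  result@candidates[best[which.min(result@candidates[best])]]
}

#' Classify events into low and high expressors at a threshold
#'
#' Events with fluorescence at or above the threshold count as high
#' expressors. The subpopulation ratio R = N_L / N_H is Inf-flagged when no
#' high expressors exist.
#'
#' @param events an [EventTable-class].
#' @param threshold fluorescence threshold theta, a.u. (> 0).
#' @return A [SubpopulationSummary-class].
#' @export
classifySubpopulations <- function(events, threshold = defaultThreshold()) {
  stopifnot(is(events, "EventTable"), threshold > 0)
  fl <- fluorescence(events)
  hi <- fl >= threshold
  nH <- sum(hi); nL <- sum(!hi)
  st <- expressionSummary(events)
  new("SubpopulationSummary", nLow = nL, nHigh = nH,
      ratio = if (nH > 0) nL / nH else Inf, ratioInfinite = nH == 0,
      meanLow = if (nL > 0) mean(fl[!hi]) else NA_real_,
      meanHigh = if (nH > 0) mean(fl[hi]) else NA_real_,
      meanAll = st[["mean"]], cv = st[["cv"]], threshold = threshold)
}

#' Mean and coefficient of variation of reporter expression
#'
#' Arithmetic mean of fluorescence and CV = population SD / mean (the SD
#' divides by n, not n - 1).
#'
#' @param events an [EventTable-class] with at least 2 events.
#' @return Named vector \code{c(mean = ..., cv = ..., n = ...)}.
#' @export
expressionSummary <- function(events) {
  stopifnot(is(events, "EventTable"))
  fl <- fluorescence(events)
  if (length(fl) < 2) stop("need at least 2 events")
  m <- mean(fl)
  sdPop <- sqrt(mean((fl - m)^2))
  c(mean = m, cv = sdPop / m, n = length(fl))
}
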