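# Fitness (population growth rate) estimation from growth curves.

#' Pointwise fitness estimate from successive cell counts
#'
#' The growth rate over each interval is
#' \eqn{g_k = \ln(N_{k+1}/N_k)/\Delta t_k}; the estimate is the mean over
#' intervals with its standard error.
#'
#' @param curve a [GrowthCurve-class] (>= 2 points, positive counts).
#' @return A [FitnessEstimate-class] with method "pointwise".
#' @export
fitnessPointwise <- function(curve) {
  stopifnot(is(curve, "GrowthCurve"))
  g <- diff(log(curve@counts)) / diff(curve@times)
  se <- if (length(g) > 1) stats::sd(g) / sqrt(length(g)) else NA_real_
  new("FitnessEstimate", g = mean(g), se = se, method = "pointwise",
      nPointsUsed = length(curve@times))
}

#' Fitness from an ordinary least-squares fit of log counts vs time
#'
#' For drug-exposure curves the pipeline default retains the last six time
#' points (\code{lastN = 6}) to minimize the transient right after drug
#' onset; alternatively an initial stretch can be dropped.
#'
#' @param curve a [GrowthCurve-class].
#' @param lastN if not NULL, keep only the last \code{lastN} points.
#' @param dropInitial number of initial points to drop (ignored when
#'   \code{lastN} is given).
#' @return A [FitnessEstimate-class] with method "linear_fit".
#' @export
fitnessLinearFit <- function(curve, lastN = NULL, dropInitial = 0) {
  stopifnot(is(curve, "GrowthCurve"))
  n <- length(curve@times)
  keep <- if (!is.null(lastN)) seq.int(max(1L, n - lastN + 1L), n)
          else seq.int(dropInitial + 1L, n)
  if (length(keep) < 2) stop("fewer than 2 points retained for the fit")
  tt <- curve@times[keep]
  ln <- log(curve@counts[keep])
  fit <- stats::lm(ln ~ tt)
  n <- length(keep)
  se <- if (n > 2) {
    s2 <- sum(stats::residuals(fit)^2) / (n - 2)
    sqrt(s2 / sum((tt - mean(tt))^2))
  } else NA_real_
  new("FitnessEstimate", g = unname(stats::coef(fit)["tt"]), se = se,
      method = "linear_fit", nPointsUsed = length(keep))
}

#' Coefficient of determination of fitness predictions
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} about the observed mean. Negative
#' values are reported as-is: a model can explain less than the mean does.
#'
#' @param predicted,observed numeric vectors of equal length (>= 2).
#' @return R-squared (dimensionless, may be negative).
#' @export
rSquared <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0) stop("observed values have zero variance; R^2 undefined")
  1 - sum((observed - predicted)^2) / ssTot
}
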