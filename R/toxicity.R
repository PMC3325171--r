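# Instantaneous (single-cell) fitness model: marginal fitness reductions for
# the antibiotic (gamma1) and the inducer-bound transactivator (gamma2),
# their Bliss product, the fast-switching overall-fitness average, and
# parameter fitting against marginal dose-response data.

#' Steady-state intracellular antibiotic concentration
#'
#' Mass-action steady state of the closed exchange/binding/turnover system:
#' the antibiotic crosses the membrane at rate hZ, binds the resistance
#' protein irreversibly at rate s, and the protein turns over at rate d,
#' under the constraint that total fluorescence F equals free plus bound
#' protein:
#' \deqn{h_Z (Z - Z_i) = s Z_i R_u, \quad B = s Z_i R_u / d, \quad
#'       F = R_u + B.}
#' Substituting R_u = F / (1 + s Z_i / d) into the exchange balance turns it
#' into a quadratic in \eqn{Z_i} whose single root in \eqn{[0, Z]} is taken
#' in a cancellation-safe form (the balance residual is monotone, so the
#' root is unique). Inputs in mg/ml and a.u. are mapped to the model's
#' intracellular unit scale by the calibration factors in \code{params}.
#'
#' @param f fluorescence, a.u. (vectorized).
#' @param z extracellular Zeocin, mg/ml (vectorized, recycled).
#' @param params a [ZeocinToxicity-class].
#' @return Data frame with columns \code{Zi}, \code{Ru}, \code{B} in model
#'   units; \code{Ru + B} equals \code{fluorUnits * f} exactly.
#' @export
intracellularZeocin <- function(f, z, params = zeocinToxicity()) {
  stopifnot(is(params, "ZeocinToxicity"), all(f >= 0), all(z >= 0))
  n <- max(length(f), length(z))
  f <- rep_len(f, n); z <- rep_len(z, n)
  hZ <- params@hZ; s <- params@s; d <- params@d
  Fm <- params@fluorUnits * f
  Zm <- params@zeocinUnits * z
  # Zi^2 + (a + b - Zm) Zi - a Zm = 0,  a = d/s,  b = d Fm / hZ
  a <- d / s
  b <- d * Fm / hZ
  q <- a + b - Zm
  disc <- sqrt(q^2 + 4 * a * Zm)
  Zi <- ifelse(q <= 0, (-q + disc) / 2, 2 * a * Zm / (q + disc))
  Zi[Zm == 0] <- 0
  Zi <- pmin(Zi, Zm)
  Ru <- Fm / (1 + s * Zi / d)
  data.frame(Zi = Zi, Ru = Ru, B = Fm - Ru)
}

#' Marginal fitness reduction under the antibiotic (gamma1)
#'
#' DNA is damaged by free intracellular antibiotic and repaired at a constant
#' rate; at steady state the division rate is reduced by
#' \deqn{\gamma_1(F, Z) = 1 / (1 + \chi Z_i^{\varphi})}
#' with \eqn{Z_i} from [intracellularZeocin()]. Strictly decreasing in Z at
#' fixed F and strictly increasing in F at fixed Z > 0 (more resistance
#' protein soaks up more antibiotic).
#'
#' @param f fluorescence, a.u.
#' @param z extracellular Zeocin, mg/ml.
#' @param params a [ZeocinToxicity-class].
#' @return Fitness reduction in (0, 1]; 1 when Z = 0.
#' @export
gammaZeocin <- function(f, z, params = zeocinToxicity()) {
  zi <- intracellularZeocin(f, z, params)$Zi
  1 / (1 + params@chi * zi^params@phi)
}

#' Marginal fitness reduction from the inducer-bound transactivator (gamma2)
#'
#' Activated transactivator molecules are toxic in proportion to their
#' abundance (fluorescence as proxy) and to inducer occupancy:
#' \deqn{\gamma_2(F, C) = 1 / (1 + \alpha \hat F \, C/(\beta + C))}
#' with \eqn{\hat F = F / \code{fluorRef}}. Equals 1 at C = 0 and saturates
#' at \eqn{1/(1 + \alpha \hat F)} for large C.
#'
#' @param f fluorescence, a.u.
#' @param atc ATc concentration, ng/ml.
#' @param params an [AtcToxicity-class].
#' @return Fitness reduction in (0, 1].
#' @export
gammaAtc <- function(f, atc, params = atcToxicity()) {
  stopifnot(is(params, "AtcToxicity"), all(f >= 0), all(atc >= 0))
  1 / (1 + params@alpha * (f / params@fluorRef) * atc / (params@beta + atc))
}

#' Joint instantaneous fitness reduction (Bliss independence)
#'
#' The two toxicities act through unrelated mechanisms, so their joint effect
#' is the product of the marginals: gamma = gamma1 * gamma2.
#'
#' @param f fluorescence, a.u.
#' @param atc ATc, ng/ml.
#' @param zeocin Zeocin, mg/ml.
#' @param zeoParams a [ZeocinToxicity-class].
#' @param atcParams an [AtcToxicity-class].
#' @param combiner function combining the two marginals (default \code{`*`};
#'   pluggable for non-Bliss interaction variants).
#' @return Joint fitness reduction in (0, 1].
#' @export
gammaJoint <- function(f, atc, zeocin, zeoParams = zeocinToxicity(),
                       atcParams = atcToxicity(), combiner = `*`) {
  combiner(gammaZeocin(f, zeocin, zeoParams), gammaAtc(f, atc, atcParams))
}

#' Overall population fitness in the fast-switching limit
#'
#' Assuming transitions across the expression distribution are much faster
#' than division, the population keeps its stationary distribution p(F)
#' under selection and the overall fitness is the distribution-weighted
#' average of instantaneous fitness:
#' \deqn{g_T = g_0 \sum_F \gamma(F, C, Z)\, p(F)}
#' evaluated at the (geometric) bin centers.
#'
#' @param dist a [FluorescenceDistribution-class].
#' @param atc ATc, ng/ml.
#' @param zeocin Zeocin, mg/ml.
#' @param zeoParams,atcParams toxicity parameters.
#' @param g0 maximal fitness, per hour (default from \code{atcParams}).
#' @return Overall fitness, per hour.
#' @export
overallFitness <- function(dist, atc, zeocin, zeoParams = zeocinToxicity(),
                           atcParams = atcToxicity(), g0 = atcParams@g0) {
  stopifnot(is(dist, "FluorescenceDistribution"))
  p <- probMass(dist)  # errors if empty; sums to 1 by construction
  if (abs(sum(p) - 1) > 1e-12) stop("distribution is not normalized")
  fc <- binCenters(dist)
  g0 * sum(gammaJoint(fc, atc, zeocin, zeoParams, atcParams) * p)
}

# shared Nelder-Mead driver: minimize fn over log-parameters with 5
# log-spaced multi-starts around the supplied initial point, then polish.
nmFitLog <- function(init, fn) {
  starts <- lapply(10^seq(-1, 1, length.out = 5), function(sc) log(init * sc))
  best <- NULL
  for (s0 in starts) {
    opt <- stats::optim(s0, fn, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish from the best point
  opt <- stats::optim(best$par, fn, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-14))
  if (opt$value <= best$value) best <- opt
  if (!is.finite(best$value))
    stop("marginal fit failed to converge; trace: ",
         paste(signif(exp(best$par), 4), collapse = ", "))
  best
}

#' Fit the Zeocin toxicity parameters to a marginal dose-response
#'
#' Least-squares fit of the fast-switching prediction to overall fitness
#' measured at increasing Zeocin concentrations without inducer. Fitness per
#' curve is estimated by [fitnessLinearFit()] over the last six points (the
#' drug-exposure default). The free parameters are (g0, phi, chi, s); the
#' membrane exchange and turnover rates stay fixed at hZ = 0.5, d = 0.25.
#' Nelder-Mead on log-parameters with five log-spaced starts.
#'
#' @param curves list of [GrowthCurve-class] at ATc = 0 spanning >= 4 Zeocin
#'   levels including Z = 0.
#' @param dist the stationary [FluorescenceDistribution-class] at ATc = 0.
#' @param init optional initial [ZeocinToxicity-class] (defaults to the
#'   package defaults).
#' @param lastN points retained per curve for fitness estimation.
#' @return List with \code{params} ([ZeocinToxicity-class]), \code{g0},
#'   \code{value} (residual sum of squares) and \code{gE} (the fitted
#'   dose-response data).
#' @export
fitZeocinToxicity <- function(curves, dist, init = zeocinToxicity(),
                              lastN = 6) {
  stopifnot(length(curves) >= 4)
  zs <- vapply(curves, function(cu) cu@zeocin, numeric(1))
  if (!any(zs == 0)) stop("need a Zeocin = 0 curve")
  if (length(unique(zs)) < 4) stop("need >= 4 distinct Zeocin levels")
  gE <- vapply(curves, function(cu) fitnessLinearFit(cu, lastN = lastN)@g,
               numeric(1))
  p0 <- c(g0 = max(gE), phi = init@phi, chi = init@chi, s = init@s)
  fc <- binCenters(dist)
  pm <- probMass(dist)
  obj <- function(lp) {
    p <- exp(lp)
    par <- zeocinToxicity(phi = p[2], chi = p[3], s = p[4], hZ = init@hZ,
                          d = init@d, zeocinUnits = init@zeocinUnits,
                          fluorUnits = init@fluorUnits)
    pred <- vapply(zs, function(z)
      p[1] * sum(gammaZeocin(fc, z, par) * pm), numeric(1))
    sum((pred - gE)^2)
  }
  best <- nmFitLog(p0, obj)
  p <- exp(best$par)
  list(params = zeocinToxicity(phi = p[2], chi = p[3], s = p[4],
                               hZ = init@hZ, d = init@d,
                               zeocinUnits = init@zeocinUnits,
                               fluorUnits = init@fluorUnits),
       g0 = unname(p[1]), value = best$value,
       gE = data.frame(zeocin = zs, g = gE))
}

#' Fit the inducer toxicity parameters to a marginal dose-response
#'
#' Same fitting contract as [fitZeocinToxicity()], for fitness measured at
#' increasing ATc without antibiotic. Free parameters: (g0, alpha, beta).
#'
#' @param curves list of [GrowthCurve-class] at Zeocin = 0 spanning >= 4 ATc
#'   levels including C = 0.
#' @param dists list of stationary [FluorescenceDistribution-class], one per
#'   curve (same order).
#' @param init optional initial [AtcToxicity-class].
#' @param lastN points retained per curve for fitness estimation.
#' @return List with \code{params} ([AtcToxicity-class], g0 filled in),
#'   \code{value} and \code{gE}.
#' @export
fitAtcToxicity <- function(curves, dists, init = atcToxicity(), lastN = 6) {
  stopifnot(length(curves) >= 4, length(curves) == length(dists))
  cs <- vapply(curves, function(cu) cu@atc, numeric(1))
  if (!any(cs == 0)) stop("need an ATc = 0 curve")
  if (length(unique(cs)) < 4) stop("need >= 4 distinct ATc levels")
  gE <- vapply(curves, function(cu) fitnessLinearFit(cu, lastN = lastN)@g,
               numeric(1))
  p0 <- c(g0 = max(gE), alpha = init@alpha, beta = init@beta)
  fhat <- lapply(dists, function(d) binCenters(d) / init@fluorRef)
  pms <- lapply(dists, probMass)
  obj <- function(lp) {
    p <- exp(lp)
    pred <- vapply(seq_along(cs), function(i)
      p[1] * sum(pms[[i]] /
                   (1 + p[2] * fhat[[i]] * cs[i] / (p[3] + cs[i]))),
      numeric(1))
    sum((pred - gE)^2)
  }
  best <- nmFitLog(p0, obj)
  p <- exp(best$par)
  list(params = atcToxicity(alpha = p[2], beta = p[3], g0 = p[1],
                            fluorRef = init@fluorRef),
       value = best$value, gE = data.frame(atc = cs, g = gE))
}
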