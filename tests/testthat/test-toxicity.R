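test_that("intracellular antibiotic steady state is self-consistent", {
  zp <- zeocinToxicity()
  # limits
  st0 <- intracellularZeocin(100, 0, zp)
  expect_equal(st0$Zi, 0)
  expect_equal(st0$Ru, zp@fluorUnits * 100)
  stF0 <- intracellularZeocin(0, 2, zp)
  expect_equal(stF0$Zi, zp@zeocinUnits * 2)  # no sink

  # random (F, Z): exchange balance and the F = Ru + B constraint hold
  set.seed(31)
  F <- runif(100, 0, 5000); Z <- runif(100, 0, 4)
  st <- intracellularZeocin(F, Z, zp)
  res <- zp@hZ * (zp@zeocinUnits * Z - st$Zi) - zp@s * st$Zi * st$Ru
  expect_lt(max(abs(res) / pmax(1, zp@hZ * zp@zeocinUnits * Z)), 1e-9)
  expect_equal(st$Ru + st$B, zp@fluorUnits * F, tolerance = 1e-12)
})

test_that("marginal fitness reductions have the right limits and
           monotonicity", {
  expect_equal(gammaZeocin(c(1, 100, 5000), 0), rep(1, 3))
  expect_equal(gammaAtc(c(1, 100, 5000), 0), rep(1, 3))

  # finite-difference monotonicity over a grid: gamma1 decreasing in Z,
  # increasing in F at Z > 0; strict except where protection is complete to
  # double precision (gamma1 == 1 exactly)
  Fg <- 10^seq(0, 4, length.out = 25)
  Zg <- c(0.25, 0.5, 1, 2, 4)
  g1 <- outer(Fg, Zg, gammaZeocin)
  dZ <- diff(t(g1)); dF <- diff(g1)
  expect_true(all(dZ <= 0) && all(dF >= 0))
  sat <- function(m) (m[-1, ] >= 1 - 1e-12) | (m[-nrow(m), ] >= 1 - 1e-12)
  satZ <- sat(t(g1))
  satF <- sat(g1)
  expect_true(all(dZ[!satZ] < 0))
  expect_true(all(dF[!satF] > 0))

  # gamma2 decreasing in both F and C; algebraic saturation at large C
  Cg <- c(0.5, 1, 2, 5, 10, 20, 50)
  g2 <- outer(Fg, Cg, gammaAtc)
  expect_true(all(diff(g2) < 0))
  expect_true(all(diff(t(g2)) < 0))
  tox <- atcToxicity()
  expect_equal(gammaAtc(300, 1e9, tox),
               1 / (1 + tox@alpha * 300 / tox@fluorRef), tolerance = 1e-6)

  # Bliss product: equals the brute-force product, bounded by each marginal
  set.seed(5)
  F <- runif(50, 1, 5000); C <- runif(50, 0, 20); Z <- runif(50, 0, 4)
  gj <- gammaJoint(F, C, Z)
  expect_equal(gj, gammaZeocin(F, Z) * gammaAtc(F, C))
  expect_true(all(gj <= pmin(gammaZeocin(F, Z), gammaAtc(F, C)) + 1e-15))
  expect_equal(gammaJoint(F, 0, 0), rep(1, 50))
  expect_true(all(gj > 0 & gj <= 1))
})

test_that("fast-switching overall fitness is a proper distribution average", {
  # degenerate distribution at one fluorescence
  d1 <- buildHistogram(eventTable(fl1 = rep(200, 1000)))
  fc <- binCenters(d1)[which.max(binCounts(d1))]
  expect_equal(overallFitness(d1, atc = 5, zeocin = 2),
               atcToxicity()@g0 * gammaJoint(fc, 5, 2))

  # gamma == 1 everywhere returns g0, and bounds hold
  fix <- circuitDistributions()
  d <- fix$dists[[which(fix$atc == 10)]]
  expect_equal(overallFitness(d, atc = 0, zeocin = 0), atcToxicity()@g0)
  gT <- overallFitness(d, atc = 10, zeocin = 2)
  gRange <- range(atcToxicity()@g0 * gammaJoint(binCenters(d), 10, 2))
  expect_gte(gT, gRange[1]); expect_lte(gT, gRange[2])

  # quadrature vs Monte Carlo over events drawn from p(F): within 3 SE
  ev <- generateStationaryEvents(circuitMixtureSpec(10, 2e4), seed = 21)
  dmc <- buildHistogram(ev)
  gQuad <- overallFitness(dmc, atc = 10, zeocin = 2)
  gi <- atcToxicity()@g0 * gammaJoint(fluorescence(ev), 10, 2)
  se <- sd(gi) / sqrt(length(gi))
  expect_lt(abs(gQuad - mean(gi)), 3 * se + 1e-4)
})

test_that("marginal dose-response fits recover the generating parameters", {
  fix <- circuitDistributions()
  dist0 <- fix$dists[[which(fix$atc == 0)]]
  zLv <- c(0, 0.25, 0.5, 1, 2, 4)
  truth <- zeocinToxicity()
  mkZ <- function(noise, seed) lapply(seq_along(zLv), function(i) {
    g <- overallFitness(dist0, atc = 0, zeocin = zLv[i])
    generateGrowthCurve(g, 4e6, simConfig(96, 12, noise, seed + i),
                        zeocin = zLv[i])
  })

  # noiseless self-consistent data: phi and chi back to <= 1 percent
  # (s is weakly identified from a single marginal curve; not asserted)
  fz <- fitZeocinToxicity(mkZ(0, 10), dist0)
  expect_lt(abs(fz$params@phi - truth@phi) / truth@phi, 0.01)
  expect_lt(abs(fz$params@chi - truth@chi) / truth@chi, 0.01)
  expect_lt(abs(fz$g0 - 0.4) / 0.4, 0.01)

  # optimality sanity: residual at the optimum <= residual at the truth
  residAt <- function(par, g0) {
    pred <- vapply(zLv, function(z) g0 *
      sum(gammaZeocin(binCenters(dist0), z, par) * probMass(dist0)),
      numeric(1))
    gE <- vapply(mkZ(0, 10), function(cu)
      fitnessLinearFit(cu, lastN = 6)@g, numeric(1))
    sum((pred - gE)^2)
  }
  expect_lte(fz$value, residAt(truth, 0.4) + 1e-10)

  # noisy recovery: median chi over 20 seeds within 10 percent
  chis <- vapply(1:20, function(s)
    fitZeocinToxicity(mkZ(0.02, 100 * s), dist0)$params@chi, numeric(1))
  expect_lt(abs(median(chis) - truth@chi) / truth@chi, 0.10)

  # inducer marginal: noiseless recovery of alpha, beta, g0
  atcTr <- atcToxicity()
  dists <- fix$dists
  mkC <- function(noise, seed) lapply(seq_along(fix$atc), function(i) {
    g <- overallFitness(dists[[i]], atc = fix$atc[i], zeocin = 0)
    generateGrowthCurve(g, 4e6, simConfig(96, 12, noise, seed + i),
                        atc = fix$atc[i])
  })
  fa <- fitAtcToxicity(mkC(0, 20), dists)
  expect_lt(abs(fa$params@alpha - atcTr@alpha) / atcTr@alpha, 0.01)
  expect_lt(abs(fa$params@beta - atcTr@beta) / atcTr@beta, 0.01)
  expect_lt(abs(fa$params@g0 - atcTr@g0) / atcTr@g0, 1e-4)

  # predicted overall fitness decreases with inducer
  predC <- vapply(seq_along(fix$atc), function(i)
    overallFitness(dists[[i]], atc = fix$atc[i], zeocin = 0), numeric(1))
  expect_true(all(diff(predC) < 0))
})
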