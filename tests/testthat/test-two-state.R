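test_that("spectral solution matches limits and a generic eigensolver", {
  s0 <- solveTwoState(twoStateParams(0, 0, gL = 0.1, gH = 0.3))
  expect_equal(sort(c(s0@a1, s0@a2)), c(0.1, 0.3))

  # equal growth: switching conserves total count, a1 = g
  se <- solveTwoState(twoStateParams(0.03, 0.01, gL = 0.2, gH = 0.2))
  expect_equal(se@a1, 0.2)
  expect_equal(se@a2, 0.2 - 0.04)

  # triangular case: f = 0
  expect_equal(populationFitness(twoStateParams(0.05, 0, gL = 0.3,
                                                gH = 0.1)),
               max(0.3 - 0.05, 0.1))

  set.seed(17)
  for (i in 1:50) {
    p <- twoStateParams(runif(1, 0, 0.2), runif(1, 0, 0.2),
                        runif(1, -0.1, 0.5), runif(1, -0.1, 0.5))
    ev <- eigen(matrix(c(p@gL - p@r, p@r, p@f, p@gH - p@f), 2, 2))$values
    sol <- solveTwoState(p)
    expect_equal(sort(Re(c(sol@a1, sol@a2))), sort(Re(ev)),
                 tolerance = 1e-12)
    # eigenvalue bounds on random sweeps
    a1 <- sol@a1
    expect_gte(a1, min(p@gL, p@gH) - max(p@r, p@f) - 1e-12)
    expect_lte(a1, max(p@gL, p@gH) + 1e-12)
  }
})

test_that("closed-form propagation equals numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(23)
  for (i in 1:10) {
    p <- twoStateParams(runif(1, 0, 0.1), runif(1, 0, 0.1),
                        runif(1, 0, 0.4), runif(1, 0, 0.4))
    n0 <- c(runif(1, 1, 100), runif(1, 1, 100))
    times <- seq(0, 120, 12)
    ode <- deSolve::ode(n0, times, function(t, y, par)
      list(c((p@gL - p@r) * y[1] + p@f * y[2],
             p@r * y[1] + (p@gH - p@f) * y[2])), NULL,
      rtol = 1e-11, atol = 1e-11)
    cf <- propagateTwoState(p, n0, times)
    expect_equal(cf[, "L"], unname(ode[, 2]), tolerance = 1e-9)
    expect_equal(cf[, "H"], unname(ode[, 3]), tolerance = 1e-9)
    expect_equal(ratioTrajectory(p, n0[1], n0[2], times),
                 unname(ode[, 2] / ode[, 3]), tolerance = 1e-9)
  }

  # population fitness equals the long-run slope of the simulated log
  # population within sampling error
  p <- twoStateParams(0.05, 0.02, 0.12, 0.2)
  tr <- simulateBirthSwitch(p, 5000, 5000, simConfig(480, 12, seed = 3),
                            dilutionTarget = 1e4)
  ln <- logPopulation(tr)
  late <- tr@times >= 120
  slope <- unname(coef(lm(ln[late] ~ tr@times[late]))[2])
  expect_lt(abs(slope - populationFitness(p)), 0.004)
})

test_that("switching-rate fitting recovers generating rates and is
           label-symmetric", {
  rf <- referenceSwitchingRates()
  g <- referenceDivisionRates()
  p <- twoStateParams(rf["r"], rf["f"], g["gL"], g["gH"])

  # noiseless arms at the reference parameter point: recovery within 1%
  sd0 <- generateSortingExperiment(p, purity = 0.99,
                                   simConfig(122, 12, noiseCv = 0, seed = 1))
  f0 <- fitSwitchingRates(sd0, g["gL"], g["gH"], nBoot = 0)
  expect_lt(abs(f0$params@r - rf[["r"]]) / rf[["r"]], 0.01)
  expect_lt(abs(f0$params@f - rf[["f"]]) / rf[["f"]], 0.01)

  # swapping arm labels and inverting ratios swaps the fitted rates
  sd1 <- generateSortingExperiment(p, purity = 0.99,
                                   simConfig(122, 12, noiseCv = 0.01,
                                             seed = 3))
  f1 <- fitSwitchingRates(sd1, g["gL"], g["gH"], nBoot = 0)
  swapped <- new("SortRelaxationData", times = sd1@times,
                 highSorted = 1 / sd1@lowSorted,
                 lowSorted = 1 / sd1@highSorted,
                 unsorted = 1 / sd1@unsorted)
  f2 <- fitSwitchingRates(swapped, g["gH"], g["gL"], nBoot = 0)
  expect_equal(f2$params@r, f1$params@f, tolerance = 1e-4)
  expect_equal(f2$params@f, f1$params@r, tolerance = 1e-4)
})

test_that("bootstrap confidence intervals cover the generating rates", {
  rf <- referenceSwitchingRates()
  g <- referenceDivisionRates()
  p <- twoStateParams(rf["r"], rf["f"], g["gL"], g["gH"])
  hits <- vapply(1:30, function(s) {
    sdd <- generateSortingExperiment(p, purity = 0.99,
                                     simConfig(122, 12, noiseCv = 0.01,
                                               seed = 200 + s))
    ft <- fitSwitchingRates(sdd, g["gL"], g["gH"], nBoot = 99,
                            seed = 300 + s)
    ft$ci["r", 1] <= rf[["r"]] && rf[["r"]] <= ft$ci["r", 2] &&
      ft$ci["f", 1] <= rf[["f"]] && rf[["f"]] <= ft$ci["f", 2]
  }, logical(1))
  expect_gte(sum(hits), 26)
})

test_that("lineage occupancy has the exact closed form", {
  rf <- referenceSwitchingRates()
  p <- twoStateParams(rf["r"], rf["f"])

  # closed-form window average vs fine-grid numerical quadrature
  pInf <- rf[["r"]] / sum(rf)
  pH <- function(t) pInf + (0.45 - pInf) * exp(-sum(rf) * t)
  numAvg <- integrate(pH, 0, 30, rel.tol = 1e-12)$value / 30
  expect_equal(lineageOccupancy(p, p0High = 0.45, window = 30), numAvg,
               tolerance = 1e-10)
  expect_equal(lineageOccupancy(p), pInf)

  # rates from memory: plain reciprocals, infinite memory maps to rate 0
  rm <- ratesFromMemory(24, Inf)
  expect_equal(rm@r, 1 / 24)
  expect_equal(rm@f, 0)
})

test_that("fluctuating environments reduce to known limits and show an
           interior optimum", {
  fix <- circuitDistributions()
  cal0 <- lapply(seq_along(fix$atc), function(i)
    calibrateTwoState(fix$dists[[i]], atc = fix$atc[i], zeocin = 0))
  cal2 <- lapply(seq_along(fix$atc), function(i)
    calibrateTwoState(fix$dists[[i]], atc = fix$atc[i], zeocin = 2))
  i10 <- which(fix$atc == 10)
  pn <- cal0[[i10]]$params
  pt <- cal2[[i10]]$params

  # degenerate schedule (never toxic) equals the eigenvalue fitness
  always <- simulateFluctuatingEnvironment(pn, pt, "periodic",
                                           meanNormal = 1e6, meanToxic = 0,
                                           horizon = 1200)
  expect_equal(always, populationFitness(pn), tolerance = 1e-9)

  # periodic schedule: phase invariance over many periods, and agreement
  # with the Floquet (product of matrix exponentials) oracle
  skip_if_not_installed("Matrix")
  fA <- simulateFluctuatingEnvironment(pn, pt, "periodic", 24, 24,
                                       horizon = 24 * 200)
  fB <- simulateFluctuatingEnvironment(pn, pt, "periodic", 24, 24,
                                       horizon = 24 * 200,
                                       startEnv = "toxic")
  expect_equal(fA, fB, tolerance = 1e-3)
  A <- function(p) matrix(c(p@gL - p@r, p@r, p@f, p@gH - p@f), 2, 2)
  M <- as.matrix(Matrix::expm(A(pt) * 24) %*% Matrix::expm(A(pn) * 24))
  floq <- log(max(abs(eigen(M)$values))) / 48
  expect_equal(fA, floq, tolerance = 1e-3)

  # fitness vs inducer shows an interior optimum for both schedules
  for (sched in c("periodic", "random")) {
    fit <- vapply(seq_along(fix$atc), function(i)
      simulateFluctuatingEnvironment(cal0[[i]]$params, cal2[[i]]$params,
                                     sched, 48, 48, horizon = 2000,
                                     nRealizations = 5, seed = 9),
      numeric(1))
    peak <- which.max(fit)
    expect_gt(peak, 1)
    expect_lt(peak, length(fit))
  }
})
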