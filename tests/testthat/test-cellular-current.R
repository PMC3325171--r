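test_that("downward current is zero without density and linear in growth
           rate", {
  breaks <- 10^seq(0, 4, length.out = 65)  # bin 24 ends at 10^1.5 < 50
  empty <- toyDistribution(breaks, c(rep(50, 24), rep(0, 40)))
  expect_equal(downwardCurrent(empty, 50, atc = 0), 0)

  d <- toyDistribution(breaks, rep(10, 64))
  i1 <- downwardCurrent(d, 50, atc = 0, g0 = 0.2)
  i2 <- downwardCurrent(d, 50, atc = 0, g0 = 0.4)
  expect_equal(i2, 2 * i1)
  expect_gt(i1, 0)

  expect_error(downwardCurrent(d, 0.5, atc = 0), "inside the histogram")
})

test_that("fitness-corrected currents balance and match hand quadrature", {
  fix <- circuitDistributions()
  d <- smoothHistogram(fix$dists[[which(fix$atc == 10)]],
                       method = "gaussian")

  # uniform fitness: upward and downward currents cancel exactly
  cu <- cellularCurrents(d, 50, function(F) rep(0.4, length(F)))
  expect_lt(abs(cu@net), 1e-9)
  expect_equal(cu@up, cu@down, tolerance = 1e-9)

  # expression-dependent fitness (low expressors fitter at Z = 0): cells
  # must flow upward in steady state
  fitFn <- function(F) 0.4 * gammaAtc(F, 10)
  cc <- cellularCurrents(d, 50, fitFn)
  expect_gt(cc@net, 0)
  expect_equal(cc@up, cc@down + cc@net)

  # low-side integral equals minus the high-side integral (stationarity)
  fc <- binCenters(d); dens <- smoothedCounts(d) / binWidths(d)
  gF <- fitFn(fc)
  gT <- pracma::trapz(fc, gF * dens) / pracma::trapz(fc, dens)
  lowInt <- pracma::trapz(fc[fc < 50], ((gF - gT) * dens)[fc < 50])
  highInt <- pracma::trapz(fc[fc >= 50], ((gF - gT) * dens)[fc >= 50])
  expect_lt(abs(lowInt + highInt) / abs(lowInt), 0.02)

  # four-bin toy with hand-computed trapezoid
  breaks <- c(1, 10, 100, 1000, 10000)
  toy <- toyDistribution(breaks, c(60, 40, 30, 20))
  fcT <- sqrt(breaks[-1] * breaks[-5])
  densT <- c(60, 40, 30, 20) / diff(breaks)
  gFT <- c(0.4, 0.3, 0.2, 0.1)
  gTT <- pracma::trapz(fcT, gFT * densT) / pracma::trapz(fcT, densT)
  netHand <- pracma::trapz(fcT[1:2], ((gFT - gTT) * densT)[1:2])
  ct <- cellularCurrents(toy, 50, function(F) approx(fcT, gFT, F,
                                                     rule = 2)$y,
                         gT = gTT, stationarityTol = 1)
  expect_equal(ct@net, netHand, tolerance = 1e-10)

  # inconsistent overall fitness triggers the stationarity warning
  expect_warning(cellularCurrents(d, 50, fitFn, gT = 0.9),
                 "stationarity")
})

test_that("memory definition and flags are exact", {
  breaks <- 10^seq(0, 4, length.out = 65)
  counts <- c(rep(0, 40), rep(0, 0), rep(100 / 24, 24))  # 100 cells high
  d <- toyDistribution(breaks, counts)
  cur <- new("CurrentEstimate", threshold = 50, down = 1, up = 2, net = 1,
             stationarityGap = 0)
  m <- memoryFromCurrents(d, cur)
  expect_equal(m@tauH, sum(counts[binCenters(d) >= 50]) / 1)

  zero <- new("CurrentEstimate", threshold = 50, down = 0, up = 0, net = 0,
              stationarityGap = 0)
  m0 <- memoryFromCurrents(d, zero)
  expect_true(is.infinite(m0@tauH))
  expect_true(is.infinite(m0@tauL))
})

test_that("current-based memory agrees with the single-cell dilution
           oracle", {
  # five rate conditions; ground truth from renewal statistics of the exact
  # lineage simulation (mean residence = occupancy / crossing rate)
  conds <- list(c(0.010, 0.010), c(0.020, 0.010), c(0.010, 0.005),
                c(0.015, 0.015), c(0.030, 0.015))
  spec <- mixtureSpec(lowMode = 5, highMode = 400, logSdLow = 0.15,
                      logSdHigh = 0.2)
  for (k in seq_along(conds)) {
    rf <- conds[[k]]
    sim <- simulateDilutionLineages(twoStateParams(rf[1], rf[2]),
                                    gDilution = 0.4, spec = spec,
                                    nCells = 2000, duration = 600,
                                    sampleTimes = seq(200, 600, 10),
                                    seed = 40 + k)
    d <- buildHistogram(sim$events)
    m <- estimateMemory(d, atcParams = atcToxicity(alpha = 0), g0 = 0.4)
    tauHTrue <- sim$occupancyHigh / sim$downCrossingsPerHour
    tauLTrue <- (1 - sim$occupancyHigh) / sim$downCrossingsPerHour
    expect_lt(abs(m@tauH - tauHTrue) / tauHTrue, 0.20)
    expect_lt(abs(m@tauL - tauLTrue) / tauLTrue, 0.25)

    # estimated downward current matches directly counted crossings
    cur <- cellularCurrents(smoothHistogram(d, method = "gaussian"), 50,
                            function(F) rep(0.4, length(F)))
    perCell <- cur@down / sum(binCounts(d))
    expect_lt(abs(perCell - sim$downCrossingsPerHour) /
                sim$downCrossingsPerHour, 0.15)

    # round trip: rates recovered from the estimated memories
    rec <- ratesFromMemory(m@tauL, m@tauH)
    expect_lt(abs(rec@f - rf[2]) / rf[2], 0.25)
  }
})

test_that("memory dose-response reproduces the inducer trends", {
  fix <- circuitDistributions()
  mdr <- memoryDoseResponse(fix$dists, fix$atc)

  # identical inputs give identical (flat) memory curves
  flat <- memoryDoseResponse(rep(fix$dists[5], 3), c(10, 10, 10))
  expect_equal(flat$tauH, rep(flat$tauH[1], 3))
  expect_equal(flat$tauL, rep(flat$tauL[1], 3))

  # low-state memory decreases monotonically with inducer (bimodal range)
  bi <- mdr$atc >= 1
  expect_true(all(diff(mdr$tauL[bi]) < 0))
  # high-state memory rises from the bistability onset through balanced
  # induction (above that the valley is resolution-limited: the sparse
  # inter-mode counts make tauH a noisy, conservative lower estimate)
  wr <- mdr$atc >= 1 & mdr$atc <= 10
  expect_true(all(diff(mdr$tauH[wr]) > 0))
  # an order-of-magnitude memory gap persists at saturating induction
  at20 <- mdr[mdr$atc == 20, ]
  expect_gt(at20$tauH / at20$tauL, 10)

  # balanced induction: high-state memory an order of magnitude above low
  at10 <- mdr[mdr$atc == 10, ]
  expect_gt(at10$tauH / at10$tauL, 10)

  # memories invariant to total cell number (currents and N scale together)
  d <- fix$dists[[which(fix$atc == 10)]]
  dHalf <- d; dHalf@counts <- d@counts / 2
  m1 <- estimateMemory(d); m2 <- estimateMemory(dHalf)
  expect_equal(m2@tauH, m1@tauH, tolerance = 1e-10)
  expect_equal(m2@tauL, m1@tauL, tolerance = 1e-10)
})
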