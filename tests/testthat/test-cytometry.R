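test_that("elliptical gate retains the chi-squared closed-form fraction", {
  ev <- generateStationaryEvents(mixtureSpec(nEvents = 1e5), seed = 2)
  g <- gateEvents(ev, 0.90)
  # density >= q * max  <=>  Mahalanobis^2 <= -2 log q, so for a 2-D
  # Gaussian the retained fraction is P(chi2_2 <= -2 log q) = 1 - q
  frac <- nEvents(g) / nEvents(ev)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 1e5))

  # q -> 0 retains everything
  expect_equal(nEvents(gateEvents(ev, 1e-300)), nEvents(ev))

  # same closed form at another q
  g75 <- gateEvents(ev, 0.75)
  expect_lt(abs(nEvents(g75) / nEvents(ev) - 0.25),
            3 * sqrt(0.25 * 0.75 / 1e5))

  expect_error(gateEvents(eventTable(fl1 = rep(10, 50))), "100 events")
})

test_that("histogram binning preserves counts and reports dropped events", {
  ev <- generateStationaryEvents(mixtureSpec(nEvents = 2e4), seed = 3)
  d <- buildHistogram(ev)
  expect_equal(sum(binCounts(d)) + d@dropped, 2e4)
  expect_equal(sum(probMass(d)), 1, tolerance = 1e-12)

  # all events in one bin
  one <- buildHistogram(eventTable(fl1 = rep(20, 100)), nBins = 10,
                        range = c(1, 1e3))
  expect_equal(max(probMass(one)), 1)
  expect_equal(sum(binCounts(one) > 0), 1)

  # two delta-like clusters give exactly two occupied regions
  two <- buildHistogram(eventTable(fl1 = c(rep(5, 50), rep(500, 50))),
                        nBins = 64)
  occ <- rle(binCounts(two) > 0)
  expect_equal(sum(occ$values), 2)

  # non-positive and out-of-range fluorescence dropped with count reported
  dd <- buildHistogram(eventTable(fl1 = c(10, 100, 2e4, 0.5)),
                       range = c(1, 1e4))
  expect_equal(sum(binCounts(dd)), 2)
  expect_equal(dd@dropped, 2)
})

test_that("moving-average smoothing is linear with the stated variance model", {
  ev <- generateStationaryEvents(mixtureSpec(nEvents = 1e4), seed = 4)
  d <- buildHistogram(ev)

  # window 1 is the identity
  expect_equal(smoothHistogram(d, window = 1)@smoothed, binCounts(d))

  # constant histogram unchanged in the interior
  flat <- toyDistribution(10^seq(0, 4, length.out = 101), rep(7, 100))
  sflat <- smoothHistogram(flat, window = 8)
  expect_equal(sflat@smoothed[10:90], rep(7, 81))

  # mass change recorded exactly
  s <- smoothHistogram(d, window = 32)
  expect_equal(s@massChange, sum(s@smoothed) - sum(binCounts(d)))

  # Poisson-noisy histogram: var(smoothed) ~ expectation / window interior
  set.seed(99)
  lam <- 100; W <- 32
  sm <- replicate(400, {
    noisy <- toyDistribution(10^seq(0, 4, length.out = 257),
                             rpois(256, lam))
    smoothHistogram(noisy, window = W)@smoothed[128]
  })
  expect_lt(abs(var(sm) / (lam / W) - 1), 0.35)
})

test_that("bimodality detection separates one from two modes", {
  # single mode at n = 1e4: not bimodal
  uni <- smoothHistogram(buildHistogram(generateStationaryEvents(
    mixtureSpec(fractionHigh = 0, nEvents = 1e4), seed = 5)))
  expect_false(bimodalityTest(uni)@isBimodal)

  # two equal modes >= 1.5 decades apart at n = 1e4: bimodal, threshold in
  # the inter-mode valley located by a density oracle
  evb <- generateStationaryEvents(mixtureSpec(fractionHigh = 0.5,
                                              nEvents = 1e4), seed = 6)
  bi <- bimodalityTest(smoothHistogram(buildHistogram(evb)))
  expect_true(bi@isBimodal)
  valleyOracle <- optimize(function(lf) {
    0.5 * dnorm(lf, log10(8), 0.18) + 0.5 * dnorm(lf, log10(300), 0.22)
  }, interval = c(log10(8), log10(300)))$minimum
  expect_lt(abs(log10(bi@threshold) - valleyOracle), 0.25)

  # inducer panel: unimodal without inducer, bimodal above the threshold
  fix <- circuitDistributions()
  smoothed <- lapply(fix$dists, smoothHistogram)
  calls <- vapply(smoothed, function(d) bimodalityTest(d)@isBimodal,
                  logical(1))
  expect_false(calls[fix$atc == 0])
  expect_true(all(calls[fix$atc >= 2]))

  # false-positive rate on unimodal Poisson-noisy inputs <= 5 percent
  fp <- vapply(1:200, function(s) {
    ev <- generateStationaryEvents(mixtureSpec(fractionHigh = 0,
                                               nEvents = 1e4), seed = s)
    bimodalityTest(smoothHistogram(buildHistogram(ev)))@isBimodal
  }, logical(1))
  expect_lte(mean(fp), 0.05)
})

test_that("threshold selection maximizes the z-score product", {
  oneCand <- new("BimodalityResult", isBimodal = TRUE, candidates = 42,
                 zLeft = 5, zRight = 6, threshold = NA_real_)
  expect_equal(selectThreshold(oneCand), 42)

  # z-products (16, 25): second candidate wins
  two <- new("BimodalityResult", isBimodal = TRUE, candidates = c(30, 60),
             zLeft = c(4, 5), zRight = c(4, 5), threshold = NA_real_)
  expect_equal(selectThreshold(two), 60)

  # ties break toward lower fluorescence
  tie <- new("BimodalityResult", isBimodal = TRUE, candidates = c(70, 30),
             zLeft = c(5, 5), zRight = c(5, 5), threshold = NA_real_)
  expect_equal(selectThreshold(tie), 30)

  notBi <- new("BimodalityResult", isBimodal = FALSE, candidates = numeric(0),
               zLeft = numeric(0), zRight = numeric(0),
               threshold = NA_real_)
  expect_error(selectThreshold(notBi), "constant threshold")
})

test_that("classification and expression statistics are exact and
           order-invariant", {
  # threshold above all events: everything low, ratio Inf-flagged
  lowOnly <- classifySubpopulations(eventTable(fl1 = c(5, 10, 20)), 100)
  expect_true(lowOnly@ratioInfinite)
  expect_equal(lowOnly@nHigh, 0)

  # balanced mixture at theta = 50: R within binomial CI of 1
  evb <- generateStationaryEvents(mixtureSpec(fractionHigh = 0.5,
                                              nEvents = 2e4), seed = 8)
  cl <- classifySubpopulations(evb, 50)
  pHat <- cl@nHigh / (cl@nHigh + cl@nLow)
  expect_lt(abs(pHat - 0.5), 3 * sqrt(0.25 / 2e4))

  # order invariance
  perm <- withr::with_seed(1, sample(nEvents(evb)))
  evp <- eventTable(fl1 = fluorescence(evb)[perm],
                    fsc = evb@exprs[perm, "FSC"],
                    ssc = evb@exprs[perm, "SSC"])
  clp <- classifySubpopulations(evp, 50)
  expect_equal(clp@ratio, cl@ratio)

  # hand computation: F in {1, 3} -> mean 2, population-SD CV 0.5
  st <- expressionSummary(eventTable(fl1 = c(1, 3)))
  expect_equal(st[["mean"]], 2)
  expect_equal(st[["cv"]], 0.5)
  expect_equal(expressionSummary(eventTable(fl1 = rep(7, 5)))[["cv"]], 0)

  # log-normal sample against the closed-form CV = sqrt(exp(sigma^2) - 1)
  sig <- 0.5
  fl <- withr::with_seed(2, rlnorm(2e5, meanlog = 3, sdlog = sig))
  cvTheory <- sqrt(exp(sig^2) - 1)
  expect_lt(abs(expressionSummary(eventTable(fl1 = fl))[["cv"]] - cvTheory),
            0.01)
})
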