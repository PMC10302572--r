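test_that("closed-form mean origin number follows 2^((C+D)/tau)", {
  expect_equal(meanOriginsClosedForm(CellCycleParams(40, 20, tauMin = 60)), 2)
  # slowest growth condition: lambda = 0.11/h -> tau = 378.1 min
  expect_equal(meanOriginsClosedForm(CellCycleParams(40, 20, tauMin = 378.1)),
               1.116, tolerance = 1e-3)
  # non-overlapping limit: obar -> 1 as tau -> Inf
  expect_equal(meanOriginsClosedForm(CellCycleParams(40, 20, tauMin = 1e9)),
               1, tolerance = 1e-6)
  expect_error(CellCycleParams(40, -1, tauMin = 60), "positive")
  # growth-rate constructor: C + D = 60 min gives obar = e^lambda
  expect_equal(meanOriginsClosedForm(paramsForGrowthRate(0.93)), exp(0.93))
  expect_equal(lambdaPerH(paramsForGrowthRate(0.65)), 0.65)
})

test_that("simulated run-out converges to the closed form over a (C,D,tau) grid", {
  n <- 1e5
  grid <- list(c(40, 20, 40), c(40, 20, 60), c(40, 20, 100),
               c(30, 25, 55), c(50, 15, 80))
  for (g in grid) {
    p <- CellCycleParams(g[1], g[2], tauMin = g[3])
    r <- simulateRunout(p, n, rngSeed = 17)
    fr <- originCounts(r)
    ks <- as.numeric(names(fr))
    se <- sqrt(sum(fr * (ks - meanOrigins(r))^2) / n)
    expect_lt(abs(meanOrigins(r) - meanOriginsClosedForm(p)),
              3 * se + 1e-9)
    expect_equal(sum(fr), 1)
    expect_true(all(abs(log2(ks) - round(log2(ks))) < 1e-12))
  }
})

test_that("high-origin fraction at (C+D)/tau = 1.5 equals 2^0.5 - 1", {
  p <- CellCycleParams(40, 20, tauMin = 40)  # exponent 1.5
  r <- simulateRunout(p, 1e5, rngSeed = 23)
  frac4 <- originCounts(r)[["4"]]
  pTrue <- 2^0.5 - 1
  se <- sqrt(pTrue * (1 - pTrue) / 1e5)
  expect_lt(abs(frac4 - pTrue), 3 * se)
  # exponent exactly 1: every cell carries 2 origins
  r2 <- simulateRunout(CellCycleParams(40, 20, tauMin = 60), 5000,
                       rngSeed = 2)
  expect_identical(names(originCounts(r2)), "2")
  expect_equal(meanOrigins(r2), 2)
})

test_that("age-sampling brute force reproduces the steady-state age density", {
  # oracle: under f(a) = (2 ln2 / tau) 2^(-a/tau) the fraction of cells
  # older than a* is 2^(1 - a*/tau) - 1; check at a* = tau/2
  tau <- 50
  p <- CellCycleParams(40, 10, tauMin = tau)  # exponent 1.0 keeps ages visible
  r <- simulateRunout(p, 1, rngSeed = 1)      # API sanity at n = 1
  expect_equal(sum(originCounts(r)), 1)
  set.seed(33)
  u <- runif(2e5)
  ages <- -tau * log2(1 - u / 2)
  fracOld <- mean(ages > tau / 2)
  expect_equal(fracOld, 2^0.5 - 1, tolerance = 5e-3)
})

test_that("DNA histograms concentrate at powers of two and round-trip obar", {
  p <- CellCycleParams(40, 20, tauMin = 45)
  r <- simulateRunout(p, 2e4, rngSeed = 5)
  h <- simulateDnaHistogram(r, cv = 0.03, nEvents = 5e4, rngSeed = 6)
  expect_equal(sum(h$count), 5e4)
  est <- estimateMeanOrigins(h)
  expect_false(est$lowConfidence)
  expect_lt(abs(est$meanOrigins - meanOrigins(r)) / meanOrigins(r), 0.02)
  # same seed, identical histogram
  h2 <- simulateDnaHistogram(r, cv = 0.03, nEvents = 5e4, rngSeed = 6)
  expect_identical(h$count, h2$count)
  # two-peak result resolves into two modes
  expect_setequal(names(est$fractions), names(originCounts(r)))
})

test_that("single-peak histograms give the exact peak value", {
  r <- simulateRunout(CellCycleParams(40, 20, tauMin = 60), 1000, rngSeed = 9)
  h <- simulateDnaHistogram(r, cv = 0.02, nEvents = 1e4, rngSeed = 10)
  est <- estimateMeanOrigins(h)
  expect_equal(est$meanOrigins, 2)
  # histogram-only input (no raw events) also works
  attr(h, "events") <- NULL
  expect_equal(estimateMeanOrigins(h)$meanOrigins, 2)
})

test_that("unresolvably noisy histograms are flagged low-confidence", {
  r <- simulateRunout(CellCycleParams(40, 20, tauMin = 40), 2e4, rngSeed = 3)
  h <- simulateDnaHistogram(r, cv = 0.45, nEvents = 2e4, rngSeed = 4)
  expect_true(estimateMeanOrigins(h)$lowConfidence)
})

test_that("paired simulations with doubled obar recover a 2.0 ratio", {
  # tune doubling times so the slow condition has obar = 1.15 and the fast
  # one exactly double that
  oSlow <- 1.15
  tauSlow <- 60 / log2(oSlow)
  tauFast <- 60 / log2(2 * oSlow)
  est <- function(tau, seed) {
    r <- simulateRunout(CellCycleParams(40, 20, tauMin = tau), 5e4,
                        rngSeed = seed)
    estimateMeanOrigins(simulateDnaHistogram(r, cv = 0.03, nEvents = 5e4,
                                             rngSeed = seed + 1))$meanOrigins
  }
  ratio <- est(tauFast, 100) / est(tauSlow, 200)
  expect_lt(abs(ratio - 2), 0.05)
})
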