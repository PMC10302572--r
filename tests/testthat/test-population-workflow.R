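test_that("growth-rate fits recover exact and noisy exponentials", {
  t <- seq(0, 5, by = 0.5)
  f <- fitGrowthRate(t, 0.05 * 2^t)
  expect_equal(f$lambda, log(2), tolerance = 1e-9)
  # constant series has slope zero
  expect_equal(fitGrowthRate(t, rep(3, length(t)))$lambda, 0)
  expect_error(fitGrowthRate(t, -0.05 * 2^t), "positive")
  expect_error(fitGrowthRate(c(0, 1), c(1, 2)), "at least 3")
  # noisy simulated curve at the fastest reference growth rate
  gc <- simulateGrowthCurve(0.93, durationH = 8, rngSeed = 12)
  od <- stitchDilutions(gc@timeH, gc@od600, gc@dilutionEvents)
  f2 <- fitGrowthRate(gc@timeH, od)
  expect_lt(abs(f2$lambda - 0.93), 3 * f2$se)
})

test_that("steady-state verification passes matched exponentials and fails mismatches", {
  t <- seq(0, 12, by = 0.25)
  curve <- GrowthCurve(t, 0.01 * exp(0.7 * t), 5e6 * exp(0.7 * t))
  v <- verifySteadyState(curve)
  expect_true(v$pass)
  expect_gte(v$generationsSpanned, 10)
  # different biomass and count rates must fail on the tolerance check
  bad <- GrowthCurve(t, 0.01 * exp(0.7 * t), 5e6 * exp(0.5 * t))
  vb <- verifySteadyState(bad, tolerance = 0.05)
  expect_false(vb$pass)
  expect_match(paste(vb$reasons, collapse = " "), "differ")
  # spans below 10 generations fail with an explicit reason
  short <- GrowthCurve(t[t <= 2], 0.01 * exp(0.7 * t[t <= 2]),
                       5e6 * exp(0.7 * t[t <= 2]))
  vs <- verifySteadyState(short)
  expect_false(vs$pass)
  expect_match(paste(vs$reasons, collapse = " "), "generations")
})

test_that("stitched multi-dilution curves verify and recover the rate", {
  gc <- simulateGrowthCurve(0.65, durationH = 12, rngSeed = 5)
  expect_gte(nrow(gc@dilutionEvents), 3)
  v <- verifySteadyState(gc)
  expect_true(v$pass)
  expect_lt(abs(v$lambdaOd - 0.65), 3 * v$seOd)
  expect_lt(abs(v$lambdaCount - 0.65), 3 * v$seCount)
})

test_that("mean cell mass is the intensive OD-per-count quotient", {
  expect_equal(meanCellMass(0.2, 2e8), 1)
  expect_equal(meanCellMass(0.2, 4e8), 0.5)
  expect_equal(meanCellMass(0.4, 4e8), meanCellMass(0.2, 2e8))
  expect_error(meanCellMass(0, 1e8), "positive")
  expect_error(meanCellMass(0.2, 0), "positive")
})

test_that("initiation mass follows the mass-per-origin relation", {
  expect_equal(initiationMass(1, 1), 1 / log(2))
  # mbar = 1 OD600 mL per 1e9 cells at obar = 2 is 7.21e-10 OD600 mL per cell
  expect_equal(initiationMass(1, 2) * 10, 7.21, tolerance = 1e-2)
  # homogeneity: degree 1 in the mass proxy, degree -1 in obar
  expect_equal(initiationMass(3 * 1.2, 2), 3 * initiationMass(1.2, 2))
  expect_equal(initiationMass(1.2, 3 * 2), initiationMass(1.2, 2) / 3)
  expect_error(initiationMass(-1, 2), "positive")
  expect_error(initiationMass(1, 0), "positive")
})

test_that("relative series always averages to one", {
  expect_equal(relativeSeries(c(1, 1, 1, 1)), rep(1, 4))
  expect_equal(relativeSeries(c(1, 3)), c(0.5, 1.5))
  expect_error(relativeSeries(1), "at least 2")
  set.seed(8)
  for (i in 1:20) {
    v <- rexp(sample(2:8, 1)) + 0.01
    expect_equal(mean(relativeSeries(v)), 1)
  }
})

test_that("trend classification needs both spread and monotonicity", {
  lam <- c(0.11, 0.52, 0.65, 0.93)
  up <- classifyTrend(c(1, 1.1, 1.3, 1.55), lam)
  expect_equal(up$label, "growth-rate-dependent")
  flat <- classifyTrend(c(1, 1, 1, 1), lam)
  expect_equal(flat$label, "constant")
  # large spread but non-monotone stays constant
  bumpy <- classifyTrend(c(1, 1.6, 0.9, 1.2), lam)
  expect_equal(bumpy$label, "constant")
  # small monotone spread stays constant
  mild <- classifyTrend(c(1, 1.02, 1.05, 1.10), lam)
  expect_equal(mild$label, "constant")
  expect_error(classifyTrend(1, 0.5), "at least 2")
  expect_error(classifyTrend(c(1, 2), c(0.5, 0.5)), "distinct")
})

test_that("settings comparison reproduces the threshold-offset discrepancy", {
  ss <- referenceSizeSummaries()
  gr <- referenceGrowthRates()
  vol <- ss[ss$feature == "volume" & ss$setting %in%
              c("microbej_m200", "microbej_100"), ]
  vol <- merge(vol, gr, by = "condition")
  vol$mass_proxy <- vol$mean
  vol$mean_origins <- exp(vol$growth_rate_per_h)  # CH model at C+D = 60 min
  cmp <- compareSettings(vol)
  expect_true(cmp$conflict)
  expect_equal(unname(cmp$labels[["microbej_m200"]]), "growth-rate-dependent")
  expect_equal(unname(cmp$labels[["microbej_100"]]), "constant")
  # one setting alone can never conflict
  one <- compareSettings(vol[vol$setting == "microbej_m200", ])
  expect_false(one$conflict)
  # mismatched condition sets are rejected
  broken <- vol[!(vol$setting == "microbej_100" & vol$condition == "glucose"), ]
  expect_error(compareSettings(broken), "same condition set")
})

test_that("endpoint initiation-mass ratios follow from summary volumes and obar ratio 2", {
  ss <- referenceSizeSummaries()
  vol <- function(setting, cond)
    ss$mean[ss$setting == setting & ss$condition == cond &
              ss$feature == "volume"]
  ratio <- function(setting)
    initiationMass(vol(setting, "glucose"), 2) /
      initiationMass(vol(setting, "glutamine"), 1)
  expect_equal(ratio("microbej_m200"), 1.551, tolerance = 1e-3)
  expect_equal(ratio("microbej_100"), 1.129, tolerance = 1e-3)
  expect_equal(ratio("oufti_set1"), 1.341, tolerance = 1e-3)
  expect_equal(ratio("oufti_set2"), 1.112, tolerance = 1e-3)
  expect_gt(ratio("oufti_set1"), ratio("oufti_set2"))
})

test_that("initiation-mass series objects normalize and label consistently", {
  s <- initiationMassSeries(c("a", "b"), c(0.2, 0.8), c(0.4, 1.2), c(1.1, 2.2))
  expect_s4_class(s, "InitiationMassSeries")
  expect_equal(mean(resultTable(s)$relative_mi), 1)
  expect_true(trendLabel(s) %in% c("constant", "growth-rate-dependent"))
})
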