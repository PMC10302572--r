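test_that("midline of an analytic stadium recovers length and width", {
  ct <- stadiumContour(3, 1, n = 240)
  ml <- computeMidline(ct)
  expect_false(ml$flagged)
  expect_equal(ml$arclengthUm, 3, tolerance = 0.01)
  # width samples over the central half are the cylinder diameter
  arc <- cumsum(c(0, sqrt(diff(ml$points[, 1])^2 + diff(ml$points[, 2])^2)))
  central <- arc > 0.25 * ml$arclengthUm & arc < 0.75 * ml$arclengthUm
  expect_true(all(abs(ml$widths[central] - 1) < 0.02))
  # near the poles the samples fall off toward zero
  expect_lt(ml$widths[2], 0.7)
})

test_that("nearly circular contours are flagged degenerate", {
  circle <- stadiumContour(1.0001, 1, n = 200)
  ml <- computeMidline(circle)
  expect_true(ml$flagged)
  m <- measureCell(circle)
  expect_true(m$flagged)
  expect_error(computeMidline(stadiumContour(3, 1)[1:5, ]), "at least 8")
})

test_that("measurements are invariant to rotation and vertex ordering", {
  base <- measureCell(stadiumContour(3, 1, n = 240))
  rot <- measureCell(stadiumContour(3, 1, angleRad = 37 * pi / 180,
                                    center = c(5, 2), n = 240))
  expect_equal(rot$length_um, base$length_um, tolerance = 5e-3)
  expect_equal(rot$width_um, base$width_um, tolerance = 5e-3)
  # rotating the starting vertex of the same polygon changes nothing material
  ct <- stadiumContour(2.4, 0.8, angleRad = 0.3, n = 200)
  shifted <- rbind(ct[81:nrow(ct), ], ct[1:80, ])
  a <- measureCell(ct); b <- measureCell(shifted)
  expect_equal(a$length_um, b$length_um, tolerance = 5e-3)
  expect_equal(a$width_um, b$width_um, tolerance = 5e-3)
  expect_equal(a$area_um2, b$area_um2, tolerance = 1e-9)
})

test_that("stadium contour area matches the closed form within 1%", {
  m <- measureCell(stadiumContour(3, 1, n = 300))
  expect_equal(m$area_um2, projectedArea(3, 1), tolerance = 0.01)
  m2 <- measureCell(stadiumContour(1.85, 0.55, angleRad = 1.1, n = 300))
  expect_equal(m2$area_um2, projectedArea(1.85, 0.55), tolerance = 0.01)
})

test_that("width definitions are ordered max >= fitted, max >= mean", {
  spec <- oneCellScene(L = 3.0, W = 0.8, noiseSd = 0)
  reg <- segmentCells(renderScene(spec)$image, 0.065,
                      SegmentationConfig())[[1]]
  wMean <- measureCell(reg, "mean")$width_um
  wMax <- measureCell(reg, "max")$width_um
  wFit <- measureCell(reg, "fitted")$width_um
  expect_gte(wMax, wMean)
  expect_gte(wMax, wFit)
  # caps drag the plain mean below the fitted (central) width
  expect_lt(wMean, wFit)
})

test_that("a clean rendered cell is measured to ground truth with the fitted width", {
  spec <- oneCellScene(L = 3.0, W = 0.8, noiseSd = 0)
  sc <- renderScene(spec)
  cal <- calibrateOffset(list(sc), 0.065, seq(-30, 30, by = 10))
  best <- cal$table[cal$table$offset == cal$bestOffset, ]
  expect_lt(abs(best$length_error_um), 0.1)
  expect_lt(abs(best$width_error_um), 0.05)
})

test_that("shoelace area matches pixel-count area within a perimeter band", {
  spec <- oneCellScene(L = 2.6, W = 0.7, noiseSd = 0)
  reg <- segmentCells(renderScene(spec)$image, 0.065,
                      SegmentationConfig())[[1]]
  m <- measureCell(reg)
  px <- 0.065
  pixelArea <- reg$areaPx * px^2
  perimBand <- (2 * m$length_um + pi * m$width_um) * px
  expect_gte(m$area_um2, 0)
  expect_lt(abs(m$area_um2 - pixelArea), perimBand)
})

test_that("population summaries follow the population-SD convention", {
  meas <- data.frame(length_um = c(2, 3), width_um = c(0.5, 0.7),
                     area_um2 = c(1, 2), volume_um3 = c(0.4, 0.8))
  s <- summarizePopulation(meas, "demo")
  expect_equal(s$length_mean, 2.5)
  expect_equal(s$length_sd, 0.5)  # population SD, not sample SD (~0.707)
  expect_equal(s$n, 2)
  # a single cell has SD zero under this convention
  s1 <- summarizePopulation(meas[1, ], "one")
  expect_true(all(c(s1$length_sd, s1$width_sd, s1$area_sd, s1$volume_sd) == 0))
  # duplicating the dataset changes neither means nor SDs
  s2 <- summarizePopulation(rbind(meas, meas), "dup")
  expect_equal(s2$length_mean, s$length_mean)
  expect_equal(s2$length_sd, s$length_sd)
  expect_error(summarizePopulation(meas[0, ]), "no measurements")
})

test_that("summaries of large clean synthetic populations match generating means", {
  m <- PopulationModel("glutamine", 2.11, 0.54, 0.55, 0.05,
                       growthRatePerH = 0.11)
  dims <- samplePopulation(m, 10000, rngSeed = 2)
  meas <- data.frame(length_um = dims$length_um, width_um = dims$width_um,
                     area_um2 = projectedArea(dims$length_um, dims$width_um),
                     volume_um3 = spherocylinderVolume(dims$length_um,
                                                       dims$width_um))
  s <- summarizePopulation(meas, "glutamine")
  expect_lt(abs(s$length_mean - 2.11), 3 * 0.54 / sqrt(10000) + 0.004)
  expect_lt(abs(s$width_mean - 0.55), 3 * 0.05 / sqrt(10000) + 0.001)
})
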