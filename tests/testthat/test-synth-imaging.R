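glutModel <- PopulationModel("glutamine", 2.11, 0.54, 0.55, 0.05,
                             growthRatePerH = 0.11)

test_that("sampled populations converge to the model means", {
  dims <- samplePopulation(glutModel, 10000, rngSeed = 1)
  seL <- 0.54 / sqrt(10000)
  seW <- 0.05 / sqrt(10000)
  expect_lt(abs(mean(dims$length_um) - 2.11), 3 * seL + 0.004)
  expect_lt(abs(mean(dims$width_um) - 0.55), 3 * seW + 0.001)
  expect_true(all(dims$length_um >= dims$width_um))
  expect_true(all(dims$width_um > 0))
})

test_that("zero-SD models yield identical cells and seeds are deterministic", {
  m0 <- PopulationModel("fixed", 2, 0, 0.6, 0, growthRatePerH = 0.5)
  dims <- samplePopulation(m0, 20, rngSeed = 3)
  expect_true(all(dims$length_um == 2) && all(dims$width_um == 0.6))
  a <- samplePopulation(glutModel, 50, rngSeed = 9)
  b <- samplePopulation(glutModel, 50, rngSeed = 9)
  expect_identical(a, b)
})

test_that("misconfigured models that reject most draws fail loudly", {
  bad <- PopulationModel("bad", 0.2, 0.5, 1.0, 0.5, lwCorrelation = 0,
                         growthRatePerH = 0.5)
  expect_error(samplePopulation(bad, 100, rngSeed = 1), "50%")
})

test_that("ground-truth mean volume matches direct-sampling expectation", {
  # independent oracle: raw bivariate normal + rejection, outside the package
  set.seed(101)
  Sigma <- matrix(c(0.54^2, 0.3 * 0.54 * 0.05,
                    0.3 * 0.54 * 0.05, 0.05^2), 2)
  lw <- MASS::mvrnorm(40000, c(2.11, 0.55), Sigma)
  lw <- lw[lw[, 2] > 0 & lw[, 1] >= lw[, 2], ]
  oracleMean <- mean(spherocylinderVolume(lw[, 1], lw[, 2]))
  oracleSe <- sd(spherocylinderVolume(lw[, 1], lw[, 2])) / sqrt(nrow(lw))
  dims <- samplePopulation(glutModel, 40000, rngSeed = 7)
  got <- mean(spherocylinderVolume(dims$length_um, dims$width_um))
  expect_lt(abs(got - oracleMean), 6 * oracleSe)
})

test_that("noise- and blur-free rendering reproduces the analytic footprint area", {
  spec <- oneCellScene(L = 2.5, W = 0.7, blurSigmaPx = 0, noiseSd = 0,
                       haloAmplitude = 100)
  sc <- renderScene(spec)
  mid <- (600 + 150) / 2
  px <- 0.065
  measured <- sum(sc$image < mid) * px^2
  analytic <- projectedArea(2.5, 0.7)
  # perimeter band of pixels is the discretization tolerance
  perimBand <- (2 * (2.5 - 0.7) + pi * 0.7) * px
  expect_lt(abs(measured - analytic), perimBand)
})

test_that("empty scenes render uniform background and seeds give identical rasters", {
  empty <- SceneSpec(data.frame(cell_id = integer(), x_um = numeric(),
                                y_um = numeric(), angle_rad = numeric(),
                                length_um = numeric(), width_um = numeric()),
                     imageShapePx = c(32L, 32L), noiseSd = 0, blurSigmaPx = 0)
  sc <- renderScene(empty)
  expect_true(all(sc$image == 600))
  spec <- oneCellScene(noiseSd = 8, rngSeed = 5)
  expect_identical(renderScene(spec)$image, renderScene(spec)$image)
})

test_that("rendering is translation-equivariant for whole-pixel shifts", {
  px <- 0.065
  s1 <- oneCellScene(center = c(3.0, 3.0), blurSigmaPx = 0, noiseSd = 0)
  s2 <- oneCellScene(center = c(3.0 + 7 * px, 3.0), blurSigmaPx = 0,
                     noiseSd = 0)
  i1 <- renderScene(s1)$image
  i2 <- renderScene(s2)$image
  expect_equal(i1[, 20:60], i2[, 27:67])
})

test_that("scene validity enforces phase-contrast polarity and rod invariants", {
  cells <- data.frame(cell_id = 1, x_um = 3, y_um = 3, angle_rad = 0,
                      length_um = 0.5, width_um = 0.7)
  expect_error(SceneSpec(cells), "length_um >= width_um")
  good <- oneCellScene()
  expect_error(SceneSpec(good@cells, backgroundLevel = 100, cellLevel = 200),
               "backgroundLevel")
})

test_that("generateDataset writes per-condition truth, images and a manifest", {
  outDir <- withr::local_tempdir()
  m2 <- PopulationModel("glucose", 2.88, 0.60, 0.74, 0.06,
                        growthRatePerH = 0.93)
  man <- generateDataset(list(glutModel, m2), cellsPerCondition = 8,
                         outDir = outDir, rngSeed = 2, cellsPerScene = 4L,
                         imageShapePx = c(160L, 160L))
  expect_setequal(unique(man$condition), c("glutamine", "glucose"))
  tr <- read.csv(file.path(outDir, "glutamine_truth.csv"))
  expect_equal(nrow(tr), 8)
  expect_true(all(file.exists(file.path(outDir, man$image_file))))
  img <- readSceneTiff(file.path(outDir, man$image_file[1]))
  expect_equal(dim(img), c(160L, 160L))
  # determinism of the manifest and truth under the same seed
  outDir2 <- withr::local_tempdir()
  man2 <- generateDataset(list(glutModel, m2), cellsPerCondition = 8,
                          outDir = outDir2, rngSeed = 2, cellsPerScene = 4L,
                          imageShapePx = c(160L, 160L))
  expect_identical(man, man2)
  expect_identical(tr, read.csv(file.path(outDir2, "glutamine_truth.csv")))
  expect_error(generateDataset(list(), 5, outDir), "at least one")
})
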