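#' Segment and measure one scene
#'
#' Convenience wrapper: [segmentCells()] then [measureRegions()].
#'
#' @param raster numeric matrix (counts).
#' @param pixelSizeUm pixel pitch.
#' @param config a [SegmentationConfig-class].
#' @param widthDefinition passed to [measureCell()].
#' @return per-cell measurement data.frame.
#' @export
measureScene <- function(raster, pixelSizeUm, config = SegmentationConfig(),
                         widthDefinition = "fitted") {
  measureRegions(segmentCells(raster, pixelSizeUm, config), widthDefinition)
}

#' Calibrate the threshold offset against ground truth
#'
#' Sweeps candidate offsets over one or more rendered scenes with known
#' ground truth and reports, per offset, the population-mean length and
#' width errors (measured mean minus true mean). The best offset minimizes
#' the combined normalized error. This is the synthetic analogue of
#' calibrating a segmentation setting against beads of known diameter.
#'
#' @param scenes list of rendered scenes (each a list with \code{image} and
#'   \code{truth}, as returned by [renderScene()]).
#' @param pixelSizeUm pixel pitch.
#' @param offsets candidate offsets (counts).
#' @param config base [SegmentationConfig-class].
#' @param widthDefinition default "fitted".
#' @return list: \code{table} (offset, n_cells, length_error_um,
#'   width_error_um), \code{bestOffset}.
#' @export
calibrateOffset <- function(scenes, pixelSizeUm, offsets,
                            config = SegmentationConfig(),
                            widthDefinition = "fitted") {
  stopifnot(length(offsets) >= 1, length(scenes) >= 1)
  trueL <- mean(unlist(lapply(scenes, function(s) s$truth$length_um)))
  trueW <- mean(unlist(lapply(scenes, function(s) s$truth$width_um)))
  rows <- lapply(offsets, function(off) {
    cfg <- config
    cfg@thresholdOffset <- off
    meas <- do.call(rbind, lapply(scenes, function(s)
      measureScene(s$image, pixelSizeUm, cfg, widthDefinition)))
    if (is.null(meas) || !nrow(meas))
      return(data.frame(offset = off, n_cells = 0L,
                        length_error_um = NA_real_, width_error_um = NA_real_))
    data.frame(offset = off, n_cells = nrow(meas),
               length_error_um = mean(meas$length_um) - trueL,
               width_error_um = mean(meas$width_um) - trueW)
  })
  tab <- do.call(rbind, rows)
  score <- abs(tab$length_error_um) / 0.1 + abs(tab$width_error_um) / 0.05
  best <- tab$offset[which.min(score)]
  list(table = tab, bestOffset = best)
}

#' Initiation-mass series implied by generating population models
#'
#' The ground-truth counterpart of the imaging pipeline: per condition, the
#' expected mean cell volume under the model's (length, width) distribution
#' (Monte-Carlo expectation of the spherocylinder volume) combined with the
#' closed-form Cooper-Helmstetter obar at the model's growth rate.
#'
#' @param models list of [PopulationModel-class].
#' @param nPerCondition Monte-Carlo draws per condition, default 20000.
#' @param rngSeed integer seed.
#' @param cMin,dMin C and D periods (min).
#' @param thresholdPct trend threshold, default 25.
#' @return an [InitiationMassSeries-class].
#' @export
trueInitiationMassSeries <- function(models, nPerCondition = 20000L,
                                     rngSeed = 1L, cMin = 40, dMin = 20,
                                     thresholdPct = 25) {
  conds <- vapply(models, conditionName, character(1))
  lambdas <- vapply(models, growthRate, numeric(1))
  vbar <- vapply(seq_along(models), function(i) {
    dims <- samplePopulation(models[[i]], nPerCondition,
                             rngSeed = stageSeed(rngSeed, paste0("true:", conds[i])))
    mean(spherocylinderVolume(dims$length_um, dims$width_um))
  }, numeric(1))
  obar <- vapply(lambdas, function(l)
    meanOriginsClosedForm(paramsForGrowthRate(l, cMin, dMin)), numeric(1))
  initiationMassSeries(conds, lambdas, vbar, obar, thresholdPct)
}

#' End-to-end synthetic initiation-mass pipeline
#'
#' For each condition: render synthetic scenes from the population model,
#' segment and measure them at the given (or auto-calibrated) threshold
#' offset, average the per-cell volumes into Vbar, obtain obar from a
#' simulated replication run-out at the condition's growth rate, and
#' assemble the initiation-mass series with its trend label.
#'
#' @param models list of [PopulationModel-class] (one per condition).
#' @param cellsPerCondition cells to render per condition.
#' @param rngSeed master seed.
#' @param offset threshold offset; if \code{NULL}, calibrated on the first
#'   condition's scenes over \code{calibrationOffsets}.
#' @param calibrationOffsets candidate offsets for auto-calibration.
#' @param cellsPerScene default 25.
#' @param runoutCells cells per run-out simulation, default 20000.
#' @param config base [SegmentationConfig-class].
#' @param thresholdPct trend threshold, default 25.
#' @param ... scene options passed to [sceneFromModel()].
#' @return list: \code{series} ([InitiationMassSeries-class]),
#'   \code{summaries} (per-condition summary data.frame),
#'   \code{offsetUsed}, \code{calibration} (NULL unless auto-calibrated).
#' @export
runSyntheticPipeline <- function(models, cellsPerCondition, rngSeed = 1L,
                                 offset = NULL,
                                 calibrationOffsets = seq(-40, 40, by = 10),
                                 cellsPerScene = 25L, runoutCells = 20000L,
                                 config = SegmentationConfig(),
                                 thresholdPct = 25, ...) {
  stopifnot(length(models) >= 2)
  conds <- vapply(models, conditionName, character(1))
  lambdas <- vapply(models, growthRate, numeric(1))
  sceneSets <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    nScenes <- ceiling(cellsPerCondition / cellsPerScene)
    lapply(seq_len(nScenes), function(s) {
      nHere <- min(cellsPerScene, cellsPerCondition - (s - 1L) * cellsPerScene)
      renderScene(sceneFromModel(
        m, nHere, rngSeed = stageSeed(rngSeed, paste0(conds[i], ":", s)), ...))
    })
  })
  pxs <- list(...)$pixelSizeUm
  if (is.null(pxs)) pxs <- 0.065
  calibration <- NULL
  if (is.null(offset)) {
    calibration <- calibrateOffset(sceneSets[[1]], pxs, calibrationOffsets,
                                   config)
    offset <- calibration$bestOffset
  }
  cfg <- config
  cfg@thresholdOffset <- offset
  summaries <- do.call(rbind, lapply(seq_along(models), function(i) {
    meas <- do.call(rbind, lapply(sceneSets[[i]], function(s)
      measureScene(s$image, pxs, cfg)))
    if (is.null(meas) || !nrow(meas))
      stop("no cells measured for condition ", conds[i])
    summarizePopulation(meas, conds[i])
  }))
  obar <- vapply(seq_along(models), function(i)
    meanOrigins(simulateRunout(paramsForGrowthRate(lambdas[i]), runoutCells,
                               rngSeed = stageSeed(rngSeed, paste0("runout:", conds[i])))),
    numeric(1))
  series <- initiationMassSeries(conds, lambdas, summaries$volume_mean, obar,
                                 thresholdPct)
  list(series = series, summaries = summaries, offsetUsed = offset,
       calibration = calibration)
}
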