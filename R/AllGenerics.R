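#' @name accessors
#' @title Accessors for bactomorph classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
#' @param object an object of the documented class.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("conditionName", function(object) standardGeneric("conditionName"))
#' @rdname accessors
#' @export
setMethod("conditionName", "PopulationModel", function(object) object@conditionName)

#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))
#' @rdname accessors
#' @export
setMethod("growthRate", "PopulationModel", function(object) object@growthRatePerH)

#' @rdname accessors
#' @export
setGeneric("meanOrigins", function(object) standardGeneric("meanOrigins"))
#' @rdname accessors
#' @export
setMethod("meanOrigins", "RunoutResult", function(object) object@meanOrigins)

#' @rdname accessors
#' @export
setGeneric("originCounts", function(object) standardGeneric("originCounts"))
#' @rdname accessors
#' @export
setMethod("originCounts", "RunoutResult", function(object) object@originCounts)

#' Growth rate of the doubling time in a CellCycleParams object
#' @rdname accessors
#' @export
setGeneric("lambdaPerH", function(object) standardGeneric("lambdaPerH"))
#' @rdname accessors
#' @export
setMethod("lambdaPerH", "CellCycleParams",
          function(object) 60 * log(2) / object@tauMin)

#' @rdname accessors
#' @export
setGeneric("trendLabel", function(object) standardGeneric("trendLabel"))
#' @rdname accessors
#' @export
setMethod("trendLabel", "InitiationMassSeries", function(object) object@trendLabel)

#' @rdname accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))
#' @rdname accessors
#' @export
setMethod("resultTable", "InitiationMassSeries", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SceneSpec", function(object) {
  cells <- object@cells
  if (nrow(cells)) {
    cells$area_um2 <- projectedArea(cells$length_um, cells$width_um)
    cells$volume_um3 <- spherocylinderVolume(cells$length_um, cells$width_um)
  } else {
    cells$area_um2 <- numeric(0)
    cells$volume_um3 <- numeric(0)
  }
  cells
})

setMethod("show", "PopulationModel", function(object) {
  cat("PopulationModel '", object@conditionName, "'\n", sep = "")
  cat(sprintf("  length %.2f +/- %.2f um, width %.2f +/- %.2f um (rho = %.2f)\n",
              object@lengthMeanUm, object@lengthSdUm,
              object@widthMeanUm, object@widthSdUm, object@lwCorrelation))
  cat(sprintf("  growth rate %.2f /h\n", object@growthRatePerH))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px at %.3f um/px, %d cells\n",
              object@imageShapePx[1], object@imageShapePx[2],
              object@pixelSizeUm, nrow(object@cells)))
  cat(sprintf("  background %g, cell %g, halo %g (sigma %.1f px), blur %.1f px, noise %g, seed %d\n",
              object@backgroundLevel, object@cellLevel, object@haloAmplitude,
              object@haloSigmaPx, object@blurSigmaPx, object@noiseSd,
              object@rngSeed))
})

setMethod("show", "SegmentationConfig", function(object) {
  cat(sprintf("SegmentationConfig: offset %+g counts, area [%.2f, %.2f] um2, smoothing %.1f px%s\n",
              object@thresholdOffset, object@minAreaUm2, object@maxAreaUm2,
              object@smoothingSigmaPx,
              if (object@excludeBorder) ", border excluded" else ""))
})

setMethod("show", "CellCycleParams", function(object) {
  cat(sprintf("CellCycleParams: C = %g min, D = %g min, tau = %g min (lambda = %.3f /h)\n",
              object@cMin, object@dMin, object@tauMin, lambdaPerH(object)))
})

setMethod("show", "RunoutResult", function(object) {
  cat(sprintf("RunoutResult: obar = %.3f over %d cells\n",
              object@meanOrigins, object@nCells))
  for (k in names(object@originCounts))
    cat(sprintf("  %s origins: %.1f%%\n", k, 100 * object@originCounts[[k]]))
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve: %d samples over %.2f h, %d dilution events\n",
              length(object@timeH), diff(range(object@timeH)),
              nrow(object@dilutionEvents)))
})

setMethod("show", "InitiationMassSeries", function(object) {
  cat(sprintf("InitiationMassSeries over %d conditions: %s (max pairwise %.1f%%, threshold %g%%)\n",
              nrow(object@table), object@trendLabel, object@maxPairwisePct,
              object@thresholdPct))
  print(object@table, row.names = FALSE, digits = 4)
})
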