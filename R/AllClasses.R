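#' Per-condition population model of cell dimensions
#'
#' Describes one growth condition as a truncated bivariate normal
#' distribution over (length, width) together with the condition's steady
#' state growth rate. The per-condition means and SDs are typically taken
#' from a published or measured population summary; draws violating the rod
#' invariants (L >= W > 0) are resampled.
#'
#' @slot conditionName condition label, e.g. the carbon source.
#' @slot lengthMeanUm,lengthSdUm mean and SD of cell length (µm).
#' @slot widthMeanUm,widthSdUm mean and SD of cell width (µm).
#' @slot lwCorrelation Pearson correlation between length and width draws.
#' @slot growthRatePerH steady-state growth rate lambda (1/h).
#' @seealso [PopulationModel()], [samplePopulation()], [referenceModels()]
#' @export
setClass("PopulationModel",
  representation(
    conditionName = "character",
    lengthMeanUm = "numeric", lengthSdUm = "numeric",
    widthMeanUm = "numeric", widthSdUm = "numeric",
    lwCorrelation = "numeric",
    growthRatePerH = "numeric"
  )
)

setValidity("PopulationModel", function(object) {
  msgs <- character()
  for (s in c("lengthMeanUm", "widthMeanUm"))
    if (slot(object, s) <= 0) msgs <- c(msgs, paste(s, "must be positive"))
  for (s in c("lengthSdUm", "widthSdUm"))
    if (slot(object, s) < 0) msgs <- c(msgs, paste(s, "must be >= 0"))
  if (abs(object@lwCorrelation) > 1)
    msgs <- c(msgs, "lwCorrelation must lie in [-1, 1]")
  if (object@growthRatePerH <= 0)
    msgs <- c(msgs, "growthRatePerH must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PopulationModel
#'
#' @param conditionName condition label.
#' @param lengthMeanUm,lengthSdUm mean/SD cell length (µm).
#' @param widthMeanUm,widthSdUm mean/SD cell width (µm).
#' @param lwCorrelation length-width correlation; populations of rod-shaped
#'   bacteria show a mild positive correlation, default 0.3.
#' @param growthRatePerH growth rate (1/h).
#' @return a [PopulationModel-class] object.
#' @export
#' @examples
#' PopulationModel("glutamine", 2.11, 0.54, 0.55, 0.05, growthRatePerH = 0.11)
PopulationModel <- function(conditionName, lengthMeanUm, lengthSdUm,
                            widthMeanUm, widthSdUm, lwCorrelation = 0.3,
                            growthRatePerH = 1) {
  new("PopulationModel", conditionName = conditionName,
      lengthMeanUm = lengthMeanUm, lengthSdUm = lengthSdUm,
      widthMeanUm = widthMeanUm, widthSdUm = widthSdUm,
      lwCorrelation = lwCorrelation, growthRatePerH = growthRatePerH)
}

#' Synthetic phase-contrast scene specification
#'
#' Everything needed to render one deterministic synthetic field of view:
#' the image geometry, the optical appearance (dark cells on a bright
#' background with an optional bright halo ring, Gaussian blur, additive
#' Gaussian noise) and the table of ground-truth cell poses. Intensities are
#' in arbitrary camera counts; rendered images are written as 16-bit TIFF.
#'
#' @slot imageShapePx integer c(rows, cols) of the raster.
#' @slot pixelSizeUm pixel pitch (µm/px).
#' @slot cells data.frame with columns \code{cell_id, x_um, y_um, angle_rad,
#'   length_um, width_um} (poses in image frame, origin at the top-left
#'   pixel centre, x rightward, y downward).
#' @slot blurSigmaPx Gaussian blur sigma (px).
#' @slot noiseSd additive Gaussian noise SD (counts).
#' @slot backgroundLevel,cellLevel background and cell-interior intensities
#'   (counts); background must exceed cell level (phase-contrast polarity).
#' @slot haloAmplitude peak brightness of the halo ring above background
#'   (counts); 0 disables the halo.
#' @slot haloSigmaPx radial width of the halo ring (px).
#' @slot rngSeed seed for the noise stream.
#' @seealso [SceneSpec()], [renderScene()]
#' @export
setClass("SceneSpec",
  representation(
    imageShapePx = "integer", pixelSizeUm = "numeric",
    cells = "data.frame",
    blurSigmaPx = "numeric", noiseSd = "numeric",
    backgroundLevel = "numeric", cellLevel = "numeric",
    haloAmplitude = "numeric", haloSigmaPx = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msgs <- character()
  if (length(object@imageShapePx) != 2L || any(object@imageShapePx < 8L))
    msgs <- c(msgs, "imageShapePx must be two integers >= 8")
  if (object@pixelSizeUm <= 0) msgs <- c(msgs, "pixelSizeUm must be positive")
  if (object@backgroundLevel <= object@cellLevel)
    msgs <- c(msgs, "backgroundLevel must exceed cellLevel (dark cells)")
  if (object@blurSigmaPx < 0 || object@noiseSd < 0 ||
      object@haloAmplitude < 0 || object@haloSigmaPx <= 0)
    msgs <- c(msgs, "blur/noise/halo parameters must be non-negative")
  need <- c("cell_id", "x_um", "y_um", "angle_rad", "length_um", "width_um")
  if (!all(need %in% names(object@cells)))
    msgs <- c(msgs, paste("cells must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@cells) &&
           (any(object@cells$width_um <= 0) ||
            any(object@cells$length_um < object@cells$width_um)))
    msgs <- c(msgs, "every cell must satisfy length_um >= width_um > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults emulate a 100x oil objective with an sCMOS camera
#' (0.065 µm/px), moderate diffraction blur and a bright halo — the
#' dominant phase-contrast appearance and the feature that makes the
#' segmentation threshold offset bias measured width.
#'
#' @param cells ground-truth cell table (see [SceneSpec-class]).
#' @param imageShapePx c(rows, cols), default 512 x 512.
#' @param pixelSizeUm µm per pixel, default 0.065.
#' @param blurSigmaPx blur sigma in px, default 1.2.
#' @param noiseSd noise SD in counts, default 8.
#' @param backgroundLevel,cellLevel default 600 and 150 counts.
#' @param haloAmplitude default 100 counts above background.
#' @param haloSigmaPx default 1.5 px.
#' @param rngSeed noise seed, default 1.
#' @return a [SceneSpec-class] object.
#' @export
SceneSpec <- function(cells, imageShapePx = c(512L, 512L),
                      pixelSizeUm = 0.065, blurSigmaPx = 1.2, noiseSd = 8,
                      backgroundLevel = 600, cellLevel = 150,
                      haloAmplitude = 100, haloSigmaPx = 1.5, rngSeed = 1L) {
  new("SceneSpec", imageShapePx = as.integer(imageShapePx),
      pixelSizeUm = pixelSizeUm, cells = as.data.frame(cells),
      blurSigmaPx = blurSigmaPx, noiseSd = noiseSd,
      backgroundLevel = backgroundLevel, cellLevel = cellLevel,
      haloAmplitude = haloAmplitude, haloSigmaPx = haloSigmaPx,
      rngSeed = as.integer(rngSeed))
}

#' Segmentation configuration
#'
#' Parameters of the threshold-based segmenter. \code{thresholdOffset} is
#' added (in camera counts) to the automatically determined Otsu threshold;
#' cells are dark, foreground is \emph{below} the effective threshold, so a
#' positive offset moves the detected boundary outward and enlarges every
#' size parameter — the mechanism by which an "auto-threshold offset"
#' setting changes reported cell sizes.
#'
#' @slot thresholdOffset signed offset (counts) added to the Otsu threshold.
#' @slot minAreaUm2,maxAreaUm2 area filter bounds (µm^2).
#' @slot intensityBounds length-2 numeric; regions whose mean raw intensity
#'   falls outside are dropped. Use c(-Inf, Inf) to disable.
#' @slot excludeBorder drop regions touching the image border.
#' @slot smoothingSigmaPx Gaussian pre-smoothing sigma (px).
#' @seealso [SegmentationConfig()], [segmentCells()], [sweepOffsets()]
#' @export
setClass("SegmentationConfig",
  representation(
    thresholdOffset = "numeric",
    minAreaUm2 = "numeric", maxAreaUm2 = "numeric",
    intensityBounds = "numeric",
    excludeBorder = "logical",
    smoothingSigmaPx = "numeric"
  )
)

setValidity("SegmentationConfig", function(object) {
  msgs <- character()
  if (object@minAreaUm2 >= object@maxAreaUm2)
    msgs <- c(msgs, "minAreaUm2 must be < maxAreaUm2")
  if (object@smoothingSigmaPx < 0)
    msgs <- c(msgs, "smoothingSigmaPx must be >= 0")
  if (length(object@intensityBounds) != 2L ||
      object@intensityBounds[1] > object@intensityBounds[2])
    msgs <- c(msgs, "intensityBounds must be an ordered length-2 numeric")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SegmentationConfig
#'
#' @param thresholdOffset counts added to the Otsu threshold (default 0).
#' @param minAreaUm2,maxAreaUm2 area filter (default 0.3 to 20 µm^2).
#' @param intensityBounds mean-intensity filter, default disabled.
#' @param excludeBorder default TRUE.
#' @param smoothingSigmaPx default 1.
#' @return a [SegmentationConfig-class] object.
#' @export
SegmentationConfig <- function(thresholdOffset = 0, minAreaUm2 = 0.3,
                               maxAreaUm2 = 20,
                               intensityBounds = c(-Inf, Inf),
                               excludeBorder = TRUE, smoothingSigmaPx = 1) {
  new("SegmentationConfig", thresholdOffset = thresholdOffset,
      minAreaUm2 = minAreaUm2, maxAreaUm2 = maxAreaUm2,
      intensityBounds = as.numeric(intensityBounds),
      excludeBorder = excludeBorder, smoothingSigmaPx = smoothingSigmaPx)
}

#' Cooper-Helmstetter cell-cycle parameters
#'
#' The C period (replication initiation to termination), D period
#' (termination to division) and doubling time tau, all in minutes. For
#' fast-growing \emph{E. coli} C ~ 40 min and D ~ 20 min are the classic
#' values; when C + D exceeds tau, replication rounds overlap and cells
#' carry 2^k origins.
#'
#' @slot cMin,dMin,tauMin periods in minutes, all positive.
#' @seealso [CellCycleParams()], [meanOriginsClosedForm()], [simulateRunout()]
#' @export
setClass("CellCycleParams",
  representation(cMin = "numeric", dMin = "numeric", tauMin = "numeric"))

setValidity("CellCycleParams", function(object) {
  if (object@cMin <= 0 || object@dMin <= 0 || object@tauMin <= 0)
    "C, D and tau must all be positive" else TRUE
})

#' Construct CellCycleParams
#'
#' @param cMin C period (min), default 40.
#' @param dMin D period (min), default 20.
#' @param tauMin doubling time (min).
#' @return a [CellCycleParams-class] object.
#' @export
#' @examples
#' CellCycleParams(tauMin = 45)
CellCycleParams <- function(cMin = 40, dMin = 20, tauMin) {
  new("CellCycleParams", cMin = cMin, dMin = dMin, tauMin = tauMin)
}

#' Result of a replication run-out experiment (simulated or measured)
#'
#' After division and new initiations are blocked, ongoing replication runs
#' to completion, so each cell ends with a number of fully replicated
#' chromosomes equal to its oriC count at arrest — always a power of two
#' under deterministic Cooper-Helmstetter timing.
#'
#' @slot originCounts named numeric; names are origin counts (powers of
#'   two), values are population fractions summing to 1.
#' @slot meanOrigins population-averaged oriC number (obar).
#' @slot nCells number of cells behind the fractions.
#' @export
setClass("RunoutResult",
  representation(originCounts = "numeric", meanOrigins = "numeric",
                 nCells = "integer"))

setValidity("RunoutResult", function(object) {
  msgs <- character()
  k <- as.numeric(names(object@originCounts))
  if (any(is.na(k)) || any(abs(log2(k) - round(log2(k))) > 1e-9))
    msgs <- c(msgs, "originCounts names must be powers of two")
  if (abs(sum(object@originCounts) - 1) > 1e-9)
    msgs <- c(msgs, "originCounts fractions must sum to 1")
  if (length(k) && abs(sum(k * object@originCounts) - object@meanOrigins) > 1e-6)
    msgs <- c(msgs, "meanOrigins inconsistent with originCounts")
  if (object@nCells < 1L) msgs <- c(msgs, "nCells must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Growth curve of a serially diluted batch culture
#'
#' Paired time series of optical density (biomass proxy) and absolute cell
#' concentration, with the dilution events needed to stitch the series back
#' into one exponential for rate fitting.
#'
#' @slot timeH sampling times (h), strictly increasing.
#' @slot od600 optical density at 600 nm, positive.
#' @slot cellsPerMl cell concentration (1/mL), positive.
#' @slot dilutionEvents data.frame with columns \code{time_h},
#'   \code{factor} (>= 1); a factor f at time t means the culture was
#'   diluted f-fold just before the first sample at or after t.
#' @seealso [GrowthCurve()], [verifySteadyState()], [simulateGrowthCurve()]
#' @export
setClass("GrowthCurve",
  representation(timeH = "numeric", od600 = "numeric",
                 cellsPerMl = "numeric", dilutionEvents = "data.frame"))

setValidity("GrowthCurve", function(object) {
  msgs <- character()
  n <- length(object@timeH)
  if (length(object@od600) != n || length(object@cellsPerMl) != n)
    msgs <- c(msgs, "time, od600 and cellsPerMl must have equal length")
  if (n > 1 && any(diff(object@timeH) <= 0))
    msgs <- c(msgs, "timeH must be strictly increasing")
  if (any(object@od600 <= 0) || any(object@cellsPerMl <= 0))
    msgs <- c(msgs, "od600 and cellsPerMl must be positive")
  if (!all(c("time_h", "factor") %in% names(object@dilutionEvents)))
    msgs <- c(msgs, "dilutionEvents needs columns time_h, factor")
  else if (nrow(object@dilutionEvents) && any(object@dilutionEvents$factor < 1))
    msgs <- c(msgs, "dilution factors must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GrowthCurve
#'
#' @param timeH,od600,cellsPerMl equal-length numeric series.
#' @param dilutionEvents data.frame(time_h, factor); default none.
#' @return a [GrowthCurve-class] object.
#' @export
GrowthCurve <- function(timeH, od600, cellsPerMl,
                        dilutionEvents = data.frame(time_h = numeric(),
                                                    factor = numeric())) {
  new("GrowthCurve", timeH = as.numeric(timeH), od600 = as.numeric(od600),
      cellsPerMl = as.numeric(cellsPerMl),
      dilutionEvents = as.data.frame(dilutionEvents))
}

#' Initiation-mass series across growth conditions
#'
#' Per-condition initiation mass m_i = (mass proxy)/(obar ln 2), the
#' normalized (relative) series obtained by dividing by the cross-condition
#' mean, and the growth-rate-trend classification.
#'
#' @slot table data.frame with columns \code{condition, growth_rate_per_h,
#'   mass_proxy, mean_origins, mi, relative_mi}.
#' @slot trendLabel "constant" or "growth-rate-dependent".
#' @slot maxPairwisePct largest pairwise percent difference among m_i.
#' @slot thresholdPct classification threshold used.
#' @export
setClass("InitiationMassSeries",
  representation(table = "data.frame", trendLabel = "character",
                 maxPairwisePct = "numeric", thresholdPct = "numeric"))

setValidity("InitiationMassSeries", function(object) {
  msgs <- character()
  need <- c("condition", "growth_rate_per_h", "mass_proxy", "mean_origins",
            "mi", "relative_mi")
  if (!all(need %in% names(object@table)))
    msgs <- c(msgs, paste("table must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@table) &&
           abs(mean(object@table$relative_mi) - 1) > 1e-9)
    msgs <- c(msgs, "relative_mi must average to 1")
  if (!object@trendLabel %in% c("constant", "growth-rate-dependent"))
    msgs <- c(msgs, "trendLabel must be 'constant' or 'growth-rate-dependent'")
  if (length(msgs)) msgs else TRUE
})
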