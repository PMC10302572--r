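#' Otsu's threshold of an intensity raster
#'
#' Returns the threshold maximizing the between-class variance of the
#' intensity histogram (Otsu's criterion). The raster is binned into
#' \code{nBins} equal-width bins over its range; the returned value is the
#' upper edge of the best split bin, so pixels \code{<= threshold} form the
#' dark class. Implemented with cumulative moments; the test suite checks it
#' against an exhaustive search over all candidate splits and against an
#' independent library implementation.
#'
#' @param raster numeric matrix with at least two distinct values.
#' @param nBins number of histogram bins, default 256.
#' @return scalar threshold on the intensity scale of \code{raster}.
#' @export
#' @examples
#' r <- matrix(c(rep(10, 50), rep(200, 50)), 10)
#' otsuThreshold(r)
otsuThreshold <- function(raster, nBins = 256L) {
  v <- as.vector(raster)
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  if (length(u) < 2L)
    stop("constant raster: Otsu threshold is undefined")
  if (length(u) <= nBins) {
    # discrete data: exact class statistics per distinct value
    counts <- tabulate(match(v, u), length(u))
    vals <- u
  } else {
    br <- seq(u[1], u[length(u)], length.out = nBins + 1L)
    counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nBins)
    vals <- (br[-1] + br[-(nBins + 1L)]) / 2
  }
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * vals)
  muT <- mu0[length(p)]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, length(p))
  # (muT w0 - mu0)^2 / (w0 w1) = w0 w1 (mean1 - mean0)^2
  bcv[valid] <- (muT * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  if (k < length(vals)) (vals[k] + vals[k + 1L]) / 2 else vals[k]
}

#' Segment dark cells from a phase-contrast-like raster
#'
#' The raster is smoothed with a Gaussian of \code{smoothingSigmaPx}; the
#' effective threshold is Otsu's value on the smoothed raster plus the
#' configured signed \code{thresholdOffset}; foreground is the set of
#' pixels \emph{below} the effective threshold (cells are dark). Connected
#' components are labelled, filtered by area, mean raw intensity and border
#' contact, and a sub-pixel contour is extracted for each surviving region
#' as the iso-intensity line of the smoothed raster at the effective
#' threshold (marching-squares linear interpolation).
#'
#' @param raster numeric matrix in counts (rows = y, top-left origin).
#' @param pixelSizeUm pixel pitch (µm/px); required.
#' @param config a [SegmentationConfig-class].
#' @return list of regions, each a list with \code{labelId}, \code{contour}
#'   (data.frame \code{x_um, y_um}, closed implicitly), \code{areaPx},
#'   \code{meanIntensity}, \code{centroidUm}. An empty list when nothing is
#'   detected.
#' @seealso [sweepOffsets()], [measureCell()]
#' @export
segmentCells <- function(raster, pixelSizeUm, config = SegmentationConfig()) {
  if (missing(pixelSizeUm) || !is.numeric(pixelSizeUm) || pixelSizeUm <= 0)
    stop("pixelSizeUm is required and must be positive")
  stopifnot(is(config, "SegmentationConfig"))
  validObject(config)
  sm <- if (config@smoothingSigmaPx > 0)
    EBImage::gblur(raster, sigma = config@smoothingSigmaPx) else raster
  thr <- otsuThreshold(sm) + config@thresholdOffset
  fg <- sm < thr
  if (!any(fg)) return(list())
  labels <- EBImage::bwlabel(fg)
  nLab <- max(labels)
  regions <- list()
  pxArea <- pixelSizeUm^2
  h <- nrow(raster); w <- ncol(raster)
  for (id in seq_len(nLab)) {
    idx <- which(labels == id, arr.ind = TRUE)
    areaPx <- nrow(idx)
    areaUm2 <- areaPx * pxArea
    if (areaUm2 < config@minAreaUm2 || areaUm2 > config@maxAreaUm2) next
    touchesBorder <- any(idx[, 1] == 1L | idx[, 1] == h |
                         idx[, 2] == 1L | idx[, 2] == w)
    if (config@excludeBorder && touchesBorder) next
    meanInt <- mean(raster[idx])
    if (meanInt < config@intensityBounds[1] ||
        meanInt > config@intensityBounds[2]) next
    contour <- regionContour(sm, idx, thr, pixelSizeUm)
    if (is.null(contour)) next
    regions[[length(regions) + 1L]] <- list(
      labelId = id,
      contour = contour,
      areaPx = areaPx,
      meanIntensity = meanInt,
      centroidUm = c(x = mean((idx[, 2] - 1) * pixelSizeUm),
                     y = mean((idx[, 1] - 1) * pixelSizeUm)),
      touchesBorder = touchesBorder)
  }
  regions
}

# sub-pixel iso-contour of one labelled region at the effective threshold.
# Works on a margin-padded crop so contourLines sees a closed level set.
regionContour <- function(smoothed, idx, thr, pixelSizeUm) {
  margin <- 3L
  r0 <- max(1L, min(idx[, 1]) - margin); r1 <- min(nrow(smoothed), max(idx[, 1]) + margin)
  c0 <- max(1L, min(idx[, 2]) - margin); c1 <- min(ncol(smoothed), max(idx[, 2]) + margin)
  sub <- smoothed[r0:r1, c0:c1, drop = FALSE]
  # contourLines treats z[i, j] as the value at (x[i], y[j]); feed rows as x
  cl <- grDevices::contourLines(x = seq_len(nrow(sub)), y = seq_len(ncol(sub)),
                                z = sub, levels = thr)
  if (!length(cl)) return(NULL)
  cy <- mean(idx[, 1]) - r0 + 1  # centroid in crop row coords
  cx <- mean(idx[, 2]) - c0 + 1
  best <- NULL; bestArea <- 0
  for (cc in cl) {
    rows <- cc$x; cols <- cc$y
    closed <- sqrt((rows[1] - rows[length(rows)])^2 +
                   (cols[1] - cols[length(cols)])^2) < 1e-6
    if (closed && length(rows) > 3) {
      rows <- rows[-length(rows)]; cols <- cols[-length(cols)]
    }
    if (length(rows) < 8L) next
    if (!closed) next
    if (!pointInPolygon(cx, cy, cols, rows)) next
    a <- abs(polygonArea(cols, rows))
    if (a > bestArea) { bestArea <- a; best <- list(rows = rows, cols = cols) }
  }
  if (is.null(best)) return(NULL)
  data.frame(x_um = (best$cols + c0 - 2) * pixelSizeUm,
             y_um = (best$rows + r0 - 2) * pixelSizeUm)
}

#' Sweep the threshold offset and summarize measured sizes per offset
#'
#' Runs [segmentCells()] + [measureCell()] at each offset and returns the
#' per-offset population means — the package-level restatement of the
#' observation that the auto-threshold offset setting shifts every reported
#' size parameter. On halo-rendered scenes mean width and volume are
#' monotone non-decreasing in the offset.
#'
#' @param raster numeric matrix (counts).
#' @param pixelSizeUm pixel pitch.
#' @param config base [SegmentationConfig-class]; its own offset is ignored.
#' @param offsets numeric vector of offsets (length >= 1).
#' @param widthDefinition passed to [measureCell()], default "fitted".
#' @return data.frame with one row per offset: \code{offset, n_cells,
#'   length_mean, width_mean, area_mean, volume_mean} (NA when nothing was
#'   measurable).
#' @export
sweepOffsets <- function(raster, pixelSizeUm, config = SegmentationConfig(),
                         offsets, widthDefinition = "fitted") {
  stopifnot(length(offsets) >= 1)
  out <- lapply(offsets, function(off) {
    cfg <- config
    cfg@thresholdOffset <- off
    regs <- segmentCells(raster, pixelSizeUm, cfg)
    meas <- measureRegions(regs, widthDefinition)
    if (!nrow(meas))
      return(data.frame(offset = off, n_cells = 0L, length_mean = NA_real_,
                        width_mean = NA_real_, area_mean = NA_real_,
                        volume_mean = NA_real_))
    data.frame(offset = off, n_cells = nrow(meas),
               length_mean = mean(meas$length_um),
               width_mean = mean(meas$width_um),
               area_mean = mean(meas$area_um2),
               volume_mean = mean(meas$volume_um3))
  })
  do.call(rbind, out)
}

#' Measure every region in a segmentation result
#'
#' Applies [measureCell()] to each region, dropping regions flagged as
#' degenerate (aspect ratio below 1.2, failed midline).
#'
#' @param regions list from [segmentCells()].
#' @param widthDefinition "fitted", "mean" or "max".
#' @return data.frame of per-cell measurements (possibly 0 rows).
#' @export
measureRegions <- function(regions, widthDefinition = "fitted") {
  rows <- lapply(regions, function(r) {
    m <- tryCatch(measureCell(r, widthDefinition), error = function(e) NULL)
    if (is.null(m) || isTRUE(m$flagged)) return(NULL)
    data.frame(cell_id = r$labelId, length_um = m$length_um,
               width_um = m$width_um, width_definition = widthDefinition,
               area_um2 = m$area_um2, volume_um3 = m$volume_um3,
               x_um = r$centroidUm[["x"]], y_um = r$centroidUm[["y"]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(cell_id = integer(), length_um = numeric(),
                      width_um = numeric(), width_definition = character(),
                      area_um2 = numeric(), volume_um3 = numeric(),
                      x_um = numeric(), y_um = numeric()))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
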