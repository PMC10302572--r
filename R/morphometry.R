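#' Compute the midline of a cell contour
#'
#' The contour is resampled densely and equally in arclength; the two poles
#' are the farthest-apart vertex pair; the contour is split at the poles
#' into two sides, each resampled to the same node count; the midline is
#' the smoothed sequence of side-point midpoints (its endpoints coincide
#' with the poles), and the width sample at node i is the distance between
#' the paired side points. This equal-count pairing is one of several valid
#' readings of "midline by interpolation" and is robust on short rods.
#'
#' Nearly isotropic contours (aspect ratio below \code{minAspect}) have no
#' stable pole pair; they are flagged degenerate rather than measured.
#'
#' @param contour data.frame with \code{x_um, y_um} (closed polygon, last
#'   vertex not repeated), at least 8 vertices.
#' @param nNodes nodes per side, default 51.
#' @param smoothWindow moving-average window for midline smoothing,
#'   default 5.
#' @param minAspect aspect-ratio flag threshold, default 1.2.
#' @return list with \code{points} (n x 2 midline), \code{widths} (per-node
#'   width samples, µm), \code{arclengthUm}, \code{flagged} (logical),
#'   \code{poleIdx}.
#' @export
computeMidline <- function(contour, nNodes = 51L, smoothWindow = 5L,
                           minAspect = 1.2) {
  x <- contour$x_um; y <- contour$y_um
  n <- length(x)
  if (n < 8L) stop("contour must have at least 8 vertices")
  if (sqrt((x[1] - x[n])^2 + (y[1] - y[n])^2) < 1e-12) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  a <- abs(polygonArea(x, y))
  if (a <= 0) stop("degenerate contour: zero area")
  # dense equal-arclength resampling of the closed contour
  dense <- resamplePolyline(c(x, x[1]), c(y, y[1]), 256L)
  dense <- dense[-nrow(dense), , drop = FALSE]
  m <- nrow(dense)
  d2 <- as.matrix(stats::dist(dense))
  poles <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  i1 <- min(poles); i2 <- max(poles)
  lengthEstimate <- d2[i1, i2]
  widthEstimate <- 2 * a / (pi * (lengthEstimate / 2))  # ellipse-equivalent
  flagged <- (lengthEstimate / max(widthEstimate, 1e-12)) < minAspect
  side1 <- dense[i1:i2, , drop = FALSE]
  side2 <- dense[c(i2:m, 1:i1), , drop = FALSE]
  s1 <- resamplePolyline(side1[, 1], side1[, 2], nNodes)
  s2 <- resamplePolyline(side2[, 1], side2[, 2], nNodes)
  s2 <- s2[nNodes:1, , drop = FALSE]  # align direction pole1 -> pole2
  mid <- (s1 + s2) / 2
  widths <- sqrt(rowSums((s1 - s2)^2))
  mid[, 1] <- movingAverage(mid[, 1], smoothWindow)
  mid[, 2] <- movingAverage(mid[, 2], smoothWindow)
  arc <- arcLength(mid[, 1], mid[, 2])
  list(points = mid, widths = widths, arclengthUm = arc[length(arc)],
       flagged = flagged, poleIdx = c(i1, i2))
}

#' Measure one segmented cell
#'
#' Length is the midline arclength (pole to pole). Width follows the
#' selected definition, mirroring the conventions of common analysis tools:
#' \describe{
#'   \item{mean}{mean of all width samples along the midline (polar caps
#'     included, which biases the value below the cylinder diameter);}
#'   \item{max}{maximum width sample;}
#'   \item{fitted}{median of the samples over the central region, excluding
#'     one cap length (half the estimated width) at each pole — the most
#'     faithful estimate of the cylinder diameter.}
#' }
#' Area is the shoelace area of the sub-pixel contour; volume applies the
#' spherocylinder model to (length, width).
#'
#' @param region one region from [segmentCells()], or any list with a
#'   \code{contour} data.frame (\code{x_um, y_um}).
#' @param widthDefinition "fitted" (default), "mean" or "max".
#' @param ... passed to [computeMidline()].
#' @return list: \code{length_um, width_um, width_definition, area_um2,
#'   volume_um3, flagged}.
#' @export
measureCell <- function(region, widthDefinition = c("fitted", "mean", "max"),
                        ...) {
  widthDefinition <- match.arg(widthDefinition)
  contour <- if (is.data.frame(region)) region else region$contour
  ml <- computeMidline(contour, ...)
  widths <- ml$widths
  nN <- length(widths)
  inner <- widths[2:(nN - 1L)]
  w <- switch(widthDefinition,
    mean = mean(inner),
    max = max(widths),
    fitted = {
      arc <- arcLength(ml$points[, 1], ml$points[, 2])
      capUm <- stats::median(widths[arc > 0.25 * ml$arclengthUm &
                                    arc < 0.75 * ml$arclengthUm]) / 2
      central <- arc >= capUm & arc <= ml$arclengthUm - capUm
      if (sum(central) < 3L) central <- arc >= 0.25 * ml$arclengthUm &
                                        arc <= 0.75 * ml$arclengthUm
      stats::median(widths[central])
    })
  x <- contour$x_um; y <- contour$y_um
  if (sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2) < 1e-12) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  area <- abs(polygonArea(x, y))
  len <- ml$arclengthUm
  flagged <- ml$flagged || len < w
  vol <- if (flagged) NA_real_ else spherocylinderVolume(len, w)
  list(length_um = len, width_um = w, width_definition = widthDefinition,
       area_um2 = area, volume_um3 = vol, flagged = flagged)
}

#' Summarize a table of per-cell measurements
#'
#' Means and SDs of length, width, area and volume plus the cell count.
#' The SD convention is the population SD (divide by n, not n - 1), stated
#' so summary tables are reproducible bit-for-bit from fixtures.
#'
#' @param measurements data.frame with \code{length_um, width_um, area_um2,
#'   volume_um3} (e.g. from [measureRegions()]); at least one row.
#' @param condition condition label attached to the summary.
#' @return one-row data.frame: \code{condition, n}, and
#'   \code{<feature>_mean}/\code{<feature>_sd} for the four features.
#' @export
summarizePopulation <- function(measurements, condition = NA_character_) {
  if (!nrow(measurements)) stop("no measurements to summarize")
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  feats <- c(length = "length_um", width = "width_um",
             area = "area_um2", volume = "volume_um3")
  out <- data.frame(condition = condition, n = nrow(measurements),
                    stringsAsFactors = FALSE)
  for (f in names(feats)) {
    v <- measurements[[feats[[f]]]]
    out[[paste0(f, "_mean")]] <- mean(v)
    out[[paste0(f, "_sd")]] <- popSd(v)
  }
  out
}
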