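#' Sample ground-truth cell dimensions from a population model
#'
#' Draws (length, width) pairs from a bivariate normal with the model's
#' means, SDs and correlation, truncated to the rod invariants
#' L >= W > 0 by rejection. With the SDs typical of bacterial populations
#' the rejection rate is well below a percent; a rate above 50% indicates a
#' misconfigured model and is an error.
#'
#' @param model a [PopulationModel-class].
#' @param nCells number of cells to draw (>= 1).
#' @param rngSeed integer seed; the same seed reproduces the same sample.
#' @return data.frame with columns \code{cell_id, length_um, width_um,
#'   condition}.
#' @export
#' @examples
#' m <- PopulationModel("demo", 2.1, 0.5, 0.55, 0.05, growthRatePerH = 0.5)
#' head(samplePopulation(m, 5, rngSeed = 1))
samplePopulation <- function(model, nCells, rngSeed = 1L) {
  stopifnot(is(model, "PopulationModel"), nCells >= 1)
  mu <- c(model@lengthMeanUm, model@widthMeanUm)
  sds <- c(model@lengthSdUm, model@widthSdUm)
  Sigma <- diag(sds^2)
  Sigma[1, 2] <- Sigma[2, 1] <- model@lwCorrelation * sds[1] * sds[2]
  withSeed(rngSeed, {
    out <- matrix(NA_real_, 0, 2)
    drawn <- 0L
    while (nrow(out) < nCells) {
      batch <- max(nCells, 100L)
      lw <- if (all(sds == 0)) {
        matrix(rep(mu, each = batch), batch, 2)
      } else {
        MASS::mvrnorm(batch, mu, Sigma)
      }
      drawn <- drawn + batch
      ok <- lw[, 2] > 0 & lw[, 1] >= lw[, 2]
      out <- rbind(out, lw[ok, , drop = FALSE])
      if (drawn >= 200L && nrow(out) < drawn / 2)
        stop("more than 50% of draws violate L >= W > 0; ",
             "the population model is misconfigured")
    }
  })
  out <- out[seq_len(nCells), , drop = FALSE]
  data.frame(cell_id = seq_len(nCells), length_um = out[, 1],
             width_um = out[, 2], condition = model@conditionName,
             stringsAsFactors = FALSE)
}

#' Place sampled cells into a scene without overlap
#'
#' Assigns each cell a uniformly random position and orientation by
#' rejection sampling so that no two cells overlap (their stadium footprints,
#' padded by \code{marginUm}, stay disjoint) and each cell lies fully inside
#' the frame. Overlapping or touching cells are a segmentation-splitting
#' problem that this generator deliberately avoids.
#'
#' @param dims data.frame with \code{length_um}, \code{width_um} (e.g. from
#'   [samplePopulation()]).
#' @param imageShapePx c(rows, cols).
#' @param pixelSizeUm µm per px.
#' @param marginUm clearance between cells and to the border, default 0.3.
#' @param rngSeed integer seed.
#' @param maxAttempts placement attempts per cell before failing, default 1000.
#' @return the input data.frame with \code{x_um, y_um, angle_rad} added.
#' @export
placeCells <- function(dims, imageShapePx = c(512L, 512L),
                       pixelSizeUm = 0.065, marginUm = 0.3, rngSeed = 1L,
                       maxAttempts = 1000L) {
  hUm <- (imageShapePx[1] - 1) * pixelSizeUm
  wUm <- (imageShapePx[2] - 1) * pixelSizeUm
  n <- nrow(dims)
  xs <- ys <- th <- numeric(n)
  withSeed(rngSeed, {
    for (i in seq_len(n)) {
      L <- dims$length_um[i]; W <- dims$width_um[i]
      half <- L / 2 + marginUm
      if (2 * half > min(hUm, wUm))
        stop("cell ", i, " cannot fit in the frame")
      placed <- FALSE
      for (a in seq_len(maxAttempts)) {
        x <- runif(1, half, wUm - half)
        y <- runif(1, half, hUm - half)
        ang <- runif(1, 0, pi)
        if (i == 1L || !anyStadiumOverlap(x, y, ang, L, W,
                                          xs[seq_len(i - 1L)], ys[seq_len(i - 1L)],
                                          th[seq_len(i - 1L)],
                                          dims$length_um[seq_len(i - 1L)],
                                          dims$width_um[seq_len(i - 1L)],
                                          marginUm)) {
          xs[i] <- x; ys[i] <- y; th[i] <- ang
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("failed to place cell ", i, " after ", maxAttempts,
             " attempts; reduce cell count or enlarge the frame")
    }
  })
  dims$x_um <- xs; dims$y_um <- ys; dims$angle_rad <- th
  dims
}

# overlap test between one stadium and a set of stadia: distance between the
# two axis segments must exceed the sum of radii plus margin
anyStadiumOverlap <- function(x, y, ang, L, W, xs, ys, angs, Ls, Ws, margin) {
  for (j in seq_along(xs)) {
    dmin <- segmentSegmentDistance(
      segmentEndpoints(x, y, ang, L, W),
      segmentEndpoints(xs[j], ys[j], angs[j], Ls[j], Ws[j]))
    if (dmin < (W + Ws[j]) / 2 + margin) return(TRUE)
  }
  FALSE
}

segmentEndpoints <- function(x, y, ang, L, W) {
  half <- (L - W) / 2
  c(x - half * cos(ang), y - half * sin(ang),
    x + half * cos(ang), y + half * sin(ang))
}

pointSegmentDistance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
}

segmentSegmentDistance <- function(s1, s2) {
  # sample-free conservative test: min over the four endpoint-to-segment
  # distances; exact when segments do not intersect, 0-adjacent otherwise
  d <- min(pointSegmentDistance(s1[1], s1[2], s2[1], s2[2], s2[3], s2[4]),
           pointSegmentDistance(s1[3], s1[4], s2[1], s2[2], s2[3], s2[4]),
           pointSegmentDistance(s2[1], s2[2], s1[1], s1[2], s1[3], s1[4]),
           pointSegmentDistance(s2[3], s2[4], s1[1], s1[2], s1[3], s1[4]))
  if (segmentsIntersect(s1, s2)) 0 else d
}

segmentsIntersect <- function(s1, s2) {
  ccw <- function(ax, ay, bx, by, cx, cy)
    (cy - ay) * (bx - ax) > (by - ay) * (cx - ax)
  (ccw(s1[1], s1[2], s2[1], s2[2], s2[3], s2[4]) !=
     ccw(s1[3], s1[4], s2[1], s2[2], s2[3], s2[4])) &&
  (ccw(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2]) !=
     ccw(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4]))
}

#' Render a synthetic phase-contrast scene
#'
#' Renders every cell in the spec as a dark stadium (the 2-D projection of a
#' spherocylinder) on a bright background, adds an optional bright halo ring
#' just outside the cell boundary, blurs with a Gaussian of
#' \code{blurSigmaPx}, and adds seeded Gaussian noise. A pixel is interior
#' iff its centre lies within W/2 of the cell's axis segment, so at zero
#' blur and noise the below-midlevel pixel count times the pixel area equals
#' the analytic stadium area to within one perimeter of pixels.
#'
#' @param spec a [SceneSpec-class].
#' @return list with \code{image} (numeric matrix, counts; rows = y) and
#'   \code{truth} (ground-truth table as from [groundTruth()]).
#' @export
#' @examples
#' cells <- data.frame(cell_id = 1, x_um = 3, y_um = 3, angle_rad = 0.4,
#'                     length_um = 2.5, width_um = 0.7)
#' sc <- renderScene(SceneSpec(cells, imageShapePx = c(96L, 96L), noiseSd = 0))
#' range(sc$image)
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  h <- spec@imageShapePx[1]; w <- spec@imageShapePx[2]
  p <- spec@pixelSizeUm
  img <- matrix(spec@backgroundLevel, h, w)
  cells <- spec@cells
  depth <- spec@backgroundLevel - spec@cellLevel
  haloReachPx <- 4 * spec@haloSigmaPx
  for (i in seq_len(nrow(cells))) {
    L <- cells$length_um[i]; W <- cells$width_um[i]
    seg <- segmentEndpoints(cells$x_um[i], cells$y_um[i], cells$angle_rad[i], L, W)
    r0 <- W / 2
    reachUm <- r0 + (haloReachPx + 2) * p
    # bounding box in pixel indices (row = y/p + 1, col = x/p + 1)
    c0 <- max(1L, floor(min(seg[1], seg[3] ) / p - reachUm / p) + 1L)
    c1 <- min(w, ceiling(max(seg[1], seg[3]) / p + reachUm / p) + 1L)
    r0i <- max(1L, floor(min(seg[2], seg[4]) / p - reachUm / p) + 1L)
    r1i <- min(h, ceiling(max(seg[2], seg[4]) / p + reachUm / p) + 1L)
    if (c1 < c0 || r1i < r0i)
      stop("cell ", cells$cell_id[i], " lies outside the frame")
    cols <- c0:c1; rows <- r0i:r1i
    px <- (cols - 1) * p; py <- (rows - 1) * p
    gx <- matrix(px, length(rows), length(cols), byrow = TRUE)
    gy <- matrix(py, length(rows), length(cols))
    d <- matrix(pointSegmentDistance(as.vector(gx), as.vector(gy),
                                     seg[1], seg[2], seg[3], seg[4]),
                length(rows), length(cols))
    patch <- img[rows, cols, drop = FALSE]
    inside <- d <= r0
    patch[inside] <- spec@cellLevel
    if (spec@haloAmplitude > 0) {
      outside <- !inside & d <= r0 + haloReachPx * p
      if (any(outside)) {
        add <- spec@haloAmplitude *
          exp(-((d[outside] - r0) / (spec@haloSigmaPx * p))^2)
        patch[outside] <- patch[outside] + add
      }
    }
    img[rows, cols] <- patch
  }
  if (spec@blurSigmaPx > 0)
    img <- matrix(as.numeric(EBImage::gblur(img, sigma = spec@blurSigmaPx)),
                  h, w)
  if (spec@noiseSd > 0)
    img <- img + withSeed(spec@rngSeed,
                          matrix(rnorm(h * w, 0, spec@noiseSd), h, w))
  list(image = img, truth = groundTruth(spec))
}

#' Build a SceneSpec for a population model
#'
#' Convenience wrapper: sample dimensions, place them, wrap in a
#' [SceneSpec-class]. Sampling, placement and rendering noise use distinct
#' substreams derived from \code{rngSeed} via [stageSeed()].
#'
#' @param model a [PopulationModel-class].
#' @param nCells cells to place.
#' @param rngSeed master seed.
#' @param ... passed to [SceneSpec()] (image shape, optics, noise).
#' @return a [SceneSpec-class].
#' @export
sceneFromModel <- function(model, nCells, rngSeed = 1L, ...) {
  args <- list(...)
  shape <- if (!is.null(args$imageShapePx)) as.integer(args$imageShapePx)
           else c(512L, 512L)
  pxs <- if (!is.null(args$pixelSizeUm)) args$pixelSizeUm else 0.065
  dims <- samplePopulation(model, nCells, rngSeed = stageSeed(rngSeed, "sample"))
  placed <- placeCells(dims, imageShapePx = shape, pixelSizeUm = pxs,
                       rngSeed = stageSeed(rngSeed, "place"))
  args$cells <- placed
  args$rngSeed <- stageSeed(rngSeed, "noise")
  do.call(SceneSpec, args)
}

#' Generate a multi-condition synthetic dataset on disk
#'
#' For each population model, samples cells, splits them across as many
#' fields of view as needed, renders each field, and writes 16-bit TIFF
#' images plus a ground-truth CSV per condition and a manifest CSV linking
#' them. Fully deterministic under \code{rngSeed}.
#'
#' @param models list of [PopulationModel-class] objects (at least one).
#' @param cellsPerCondition number of cells per condition.
#' @param outDir output directory (created if needed).
#' @param rngSeed master seed.
#' @param cellsPerScene cells per field of view, default 25.
#' @param ... scene options passed to [sceneFromModel()].
#' @return invisibly, the manifest data.frame (columns \code{condition,
#'   scene, image_file, truth_file, n_cells}).
#' @export
generateDataset <- function(models, cellsPerCondition, outDir, rngSeed = 1L,
                            cellsPerScene = 25L, ...) {
  if (!length(models)) stop("at least one population model is required")
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory ", outDir)
  manifest <- NULL
  for (m in models) {
    stopifnot(is(m, "PopulationModel"))
    cond <- conditionName(m)
    nScenes <- ceiling(cellsPerCondition / cellsPerScene)
    truthAll <- NULL
    for (s in seq_len(nScenes)) {
      nHere <- min(cellsPerScene, cellsPerCondition - (s - 1L) * cellsPerScene)
      seedHere <- stageSeed(rngSeed, paste0(cond, ":", s))
      spec <- sceneFromModel(m, nHere, rngSeed = seedHere, ...)
      sc <- renderScene(spec)
      imgFile <- file.path(outDir, sprintf("%s_scene%03d.tif", cond, s))
      writeSceneTiff(sc$image, imgFile)
      tr <- sc$truth
      tr$scene <- s
      tr$cell_id <- tr$cell_id + (s - 1L) * cellsPerScene
      truthAll <- rbind(truthAll, tr)
      manifest <- rbind(manifest, data.frame(
        condition = cond, scene = s, image_file = basename(imgFile),
        truth_file = sprintf("%s_truth.csv", cond), n_cells = nHere,
        stringsAsFactors = FALSE))
    }
    write.csv(truthAll, file.path(outDir, sprintf("%s_truth.csv", cond)),
              row.names = FALSE)
  }
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write a counts raster as 16-bit grayscale TIFF
#'
#' Counts are scaled by \code{scaleMax} into [0, 1] (clipping) as required
#' by the TIFF writer and stored at 16 bits per sample.
#'
#' @param image numeric matrix in counts.
#' @param path output file.
#' @param scaleMax full-scale count value, default 1000.
#' @return invisibly, \code{path}.
#' @export
writeSceneTiff <- function(image, path, scaleMax = 1000) {
  # keep the first argument the matrix: pmin/pmax take attributes from it
  img <- pmin(pmax(image / scaleMax, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a TIFF written by [writeSceneTiff()] back into counts
#'
#' @param path TIFF file.
#' @param scaleMax full-scale count value used at write time.
#' @return numeric matrix in counts.
#' @export
readSceneTiff <- function(path, scaleMax = 1000) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * scaleMax
}
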