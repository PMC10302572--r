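# Analytic stadium contour: rectangle of size W x (L - W) with semicircular
# caps, rotated and translated. Vertices ordered counter-clockwise, first
# vertex not repeated.
stadiumContour <- function(L, W, angleRad = 0, center = c(0, 0), n = 200L) {
  r <- W / 2
  hl <- (L - W) / 2
  nArc <- max(8L, round(n * (pi * r) / (2 * pi * r + 2 * (L - W))))
  nSide <- max(4L, round((n - 2L * nArc) / 2))
  thR <- seq(-pi / 2, pi / 2, length.out = nArc)          # right cap
  thL <- seq(pi / 2, 3 * pi / 2, length.out = nArc)       # left cap
  xs <- c(hl + r * cos(thR),
          seq(hl, -hl, length.out = nSide),
          -hl + r * cos(thL),
          seq(-hl, hl, length.out = nSide))
  ys <- c(r * sin(thR),
          rep(r, nSide),
          r * sin(thL),
          rep(-r, nSide))
  keep <- c(TRUE, (diff(xs)^2 + diff(ys)^2) > 1e-18)
  xs <- xs[keep]; ys <- ys[keep]
  ca <- cos(angleRad); sa <- sin(angleRad)
  data.frame(x_um = center[1] + ca * xs - sa * ys,
             y_um = center[2] + sa * xs + ca * ys)
}

# one-cell scene with configurable optics, defaults clean (no noise)
oneCellScene <- function(L = 2.5, W = 0.7, angleRad = 0.4, center = c(3.2, 3),
                         shape = c(96L, 96L), noiseSd = 0, blurSigmaPx = 1.2,
                         haloAmplitude = 100, rngSeed = 1L) {
  cells <- data.frame(cell_id = 1L, x_um = center[1], y_um = center[2],
                      angle_rad = angleRad, length_um = L, width_um = W)
  SceneSpec(cells, imageShapePx = shape, noiseSd = noiseSd,
            blurSigmaPx = blurSigmaPx, haloAmplitude = haloAmplitude,
            rngSeed = rngSeed)
}

# brute-force 3-D voxelization of a spherocylinder: points within W/2 of the
# axis segment of length L - W (independent oracle for the closed form)
voxelVolume <- function(L, W, pitch = 0.008) {
  r <- W / 2
  hl <- (L - W) / 2
  xs <- seq(-L / 2 + pitch / 2, L / 2, by = pitch)
  ys <- seq(-r + pitch / 2, r, by = pitch)
  zs <- seq(-r + pitch / 2, r, by = pitch)
  count <- 0
  for (z in zs) {
    g <- expand.grid(x = xs, y = ys)
    ax <- pmin(pmax(g$x, -hl), hl)
    d2 <- (g$x - ax)^2 + g$y^2 + z^2
    count <- count + sum(d2 <= r^2)
  }
  count * pitch^3
}

# exhaustive Otsu oracle: best split over distinct 8-bit values by direct
# between-class variance evaluation; returns the split value t* such that
# the dark class is {v <= t*}
otsuBruteForce <- function(v) {
  vals <- sort(unique(v))
  best <- -Inf; bestT <- vals[1]
  for (t in vals[-length(vals)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; bestT <- t }
  }
  bestT
}
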