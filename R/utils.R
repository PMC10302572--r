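#' @import methods
#' @importFrom stats rnorm runif lm coef sd median quantile setNames complete.cases
#' @importFrom grDevices contourLines
#' @importFrom utils read.csv write.csv head tail
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's \code{.Random.seed}, seeds the default generator with
#' \code{seed}, evaluates \code{expr}, and restores the previous RNG state on
#' exit. All stochastic functions in this package route their randomness
#' through this helper so that a single integer seed makes a whole run
#' reproducible without clobbering the session RNG.
#'
#' @param seed single non-negative integer.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed == round(seed))
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage substream seed from a master seed
#'
#' One global seed fans out to named stages (image synthesis, run-out
#' simulation, noise injection, ...) so individual stages can be re-run with
#' stable randomness. The derived seed is a deterministic hash folded into
#' [0, 2^31 - 2].
#'
#' @param seed master seed (non-negative integer).
#' @param stage character scalar naming the stage.
#' @return a single integer seed.
#' @export
#' @examples
#' stageSeed(1, "render") != stageSeed(1, "runout")
stageSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483646) + 1L
}

# shoelace signed area of a closed polygon given vertex coordinates (not
# repeating the first vertex); positive for counter-clockwise orientation
polygonArea <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# even-odd rule point-in-polygon test
pointInPolygon <- function(px, py, x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  crosses <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  (sum(crosses) %% 2L) == 1L
}

# cumulative arclength of a polyline
arcLength <- function(x, y) {
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

# resample a polyline to n points equally spaced in arclength
resamplePolyline <- function(x, y, n) {
  s <- arcLength(x, y)
  if (s[length(s)] <= 0) stop("degenerate polyline with zero length")
  si <- seq(0, s[length(s)], length.out = n)
  cbind(x = stats::approx(s, x, xout = si, ties = "ordered")$y,
        y = stats::approx(s, y, xout = si, ties = "ordered")$y)
}

# centred moving average that preserves endpoints; window is forced odd
movingAverage <- function(v, window) {
  n <- length(v)
  if (window <= 1L || n < 3L) return(v)
  window <- min(window, n - (1 - n %% 2))
  if (window %% 2L == 0L) window <- window - 1L
  half <- (window - 1L) %/% 2L
  out <- v
  for (i in seq_len(n)) {
    k <- min(half, i - 1L, n - i)
    out[i] <- mean(v[(i - k):(i + k)])
  }
  out
}
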