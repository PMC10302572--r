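#' Population-averaged oriC number under steady-state growth (closed form)
#'
#' In a steady-state exponential population with deterministic
#' Cooper-Helmstetter timing, the population-averaged number of replication
#' origins per cell is \eqn{\bar o = 2^{(C+D)/\tau}}. This is the analytic
#' oracle against which the run-out simulator is checked.
#'
#' @param params a [CellCycleParams-class].
#' @return scalar obar.
#' @export
#' @examples
#' meanOriginsClosedForm(CellCycleParams(40, 20, tauMin = 60)) # 2
meanOriginsClosedForm <- function(params) {
  stopifnot(is(params, "CellCycleParams"))
  validObject(params)
  2^((params@cMin + params@dMin) / params@tauMin)
}

#' Cell-cycle parameters for a given growth rate
#'
#' Convenience constructor: doubling time tau = ln(2)/lambda converted to
#' minutes, with the classic C = 40, D = 20 min defaults.
#'
#' @param lambdaPerH growth rate (1/h), positive.
#' @param cMin,dMin C and D periods (min).
#' @return a [CellCycleParams-class].
#' @export
#' @examples
#' meanOriginsClosedForm(paramsForGrowthRate(0.93))
paramsForGrowthRate <- function(lambdaPerH, cMin = 40, dMin = 20) {
  stopifnot(lambdaPerH > 0)
  CellCycleParams(cMin, dMin, tauMin = 60 * log(2) / lambdaPerH)
}

#' Simulate a replication run-out experiment
#'
#' Samples \code{nCells} cell ages from the steady-state age distribution
#' (density \eqn{f(a) = (2\ln 2/\tau)\,2^{-a/\tau}} on \eqn{[0, \tau]}) and
#' assigns each cell its oriC count at the moment division and new
#' initiations are blocked. Writing \eqn{(C+D)/\tau = n + x} with integer
#' \eqn{n} and \eqn{x \in [0, 1)}, cells older than \eqn{\tau(1-x)} carry
#' \eqn{2^{n+1}} origins and younger cells carry \eqn{2^n}. After run-out
#' each origin has completed replication, so the distribution of fully
#' replicated chromosomes equals this origin-count distribution.
#'
#' @param params a [CellCycleParams-class].
#' @param nCells number of cells (>= 1).
#' @param rngSeed integer seed.
#' @return a [RunoutResult-class].
#' @export
#' @examples
#' simulateRunout(CellCycleParams(40, 20, tauMin = 40), 1e4, rngSeed = 1)
simulateRunout <- function(params, nCells, rngSeed = 1L) {
  stopifnot(is(params, "CellCycleParams"), nCells >= 1)
  validObject(params)
  tau <- params@tauMin
  expo <- (params@cMin + params@dMin) / tau
  n <- floor(expo)
  xfrac <- expo - n
  ages <- withSeed(rngSeed, {
    u <- runif(nCells)
    -tau * log2(1 - u / 2)  # inverse CDF of the steady-state age density
  })
  counts <- ifelse(ages > tau * (1 - xfrac), 2^(n + 1), 2^n)
  tab <- table(counts)
  fr <- as.numeric(tab) / nCells
  names(fr) <- names(tab)
  new("RunoutResult", originCounts = fr,
      meanOrigins = sum(as.numeric(names(fr)) * fr),
      nCells = as.integer(nCells))
}

#' Simulate a flow-cytometry DNA-content histogram from a run-out result
#'
#' Each cell's fluorescence is its chromosome count times a multiplicative
#' Gaussian error of coefficient of variation \code{cv} (instrument +
#' staining noise), then binned. Peaks sit at integer chromosome
#' equivalents (powers of two).
#'
#' @param result a [RunoutResult-class].
#' @param cv coefficient of variation, in (0, 0.5).
#' @param nEvents number of flow events to draw.
#' @param rngSeed integer seed.
#' @param nBins histogram bins, default 256.
#' @return data.frame \code{bin_center, count}, with attribute
#'   \code{"events"} carrying the raw per-event fluorescence.
#' @export
simulateDnaHistogram <- function(result, cv, nEvents, rngSeed = 1L,
                                 nBins = 256L) {
  stopifnot(is(result, "RunoutResult"), cv > 0, cv < 0.5, nEvents >= 1)
  ks <- as.numeric(names(result@originCounts))
  withSeed(rngSeed, {
    counts <- ks[sample.int(length(ks), nEvents, replace = TRUE,
                            prob = result@originCounts)]
    fluor <- counts * (1 + rnorm(nEvents, 0, cv))
  })
  fluor <- fluor[fluor > 0]
  br <- seq(min(fluor), max(fluor), length.out = nBins + 1L)
  if (diff(range(fluor)) == 0) br <- fluor[1] + c(-0.5, 0.5)
  h <- tabulate(findInterval(fluor, br, rightmost.closed = TRUE),
                length(br) - 1L)
  out <- data.frame(bin_center = (br[-1] + br[-length(br)]) / 2, count = h)
  attr(out, "events") <- fluor
  out
}

#' Estimate the population-averaged oriC number from a DNA histogram
#'
#' Events (or histogram mass) are assigned to the nearest power-of-two peak
#' centre in log2 fluorescence space — multiplicative noise is symmetric
#' there — and \eqn{\bar o = \sum_k 2^k f_k}. The candidate k range is taken
#' from the data range. If the within-peak spread in log2 space exceeds a
#' quarter of the unit peak spacing, peaks are not cleanly resolvable and
#' the estimate is flagged low-confidence.
#'
#' @param histogram data.frame \code{bin_center, count} as from
#'   [simulateDnaHistogram()] (the \code{"events"} attribute is used when
#'   present, otherwise bin centres weighted by counts).
#' @return list: \code{meanOrigins}, \code{fractions} (named by 2^k),
#'   \code{lowConfidence} (logical).
#' @export
estimateMeanOrigins <- function(histogram) {
  ev <- attr(histogram, "events")
  if (is.null(ev)) {
    keep <- histogram$count > 0 & histogram$bin_center > 0
    ev <- rep(histogram$bin_center[keep], histogram$count[keep])
  }
  if (!length(ev)) stop("empty histogram")
  lg <- log2(ev)
  kRange <- seq(floor(min(lg) + 0.5), ceiling(max(lg) - 0.5))
  if (!length(kRange)) kRange <- round(stats::median(lg))
  assignK <- kRange[pmax(1L, pmin(length(kRange),
                                  round(lg - kRange[1]) + 1L))]
  tab <- table(factor(assignK, levels = kRange))
  fr <- as.numeric(tab) / length(ev)
  names(fr) <- as.character(2^kRange)
  keep <- fr > 0
  fr <- fr[keep]
  resid <- lg - assignK
  lowConfidence <- stats::sd(resid) > 0.25
  list(meanOrigins = sum(as.numeric(names(fr)) * fr),
       fractions = fr, lowConfidence = lowConfidence)
}
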