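#' Fit an exponential growth rate
#'
#' Least-squares slope of ln(value) versus time: value(t) = v0 exp(lambda t).
#'
#' @param timeH times (h), at least 3.
#' @param values positive series (OD600 or cells/mL).
#' @return list: \code{lambda} (1/h), \code{se}, \code{r2}, \code{fit} (lm).
#' @export
#' @examples
#' fitGrowthRate(0:5, 0.05 * 2^(0:5))$lambda # ln 2
fitGrowthRate <- function(timeH, values) {
  if (length(timeH) < 3L) stop("need at least 3 points")
  if (any(values <= 0)) stop("values must be positive for a log-linear fit")
  fit <- lm(log(values) ~ timeH)
  # noiseless series are legitimate inputs; summary.lm warns on perfect fits
  s <- suppressWarnings(summary(fit))
  list(lambda = unname(coef(fit)[2]),
       se = s$coefficients[2, 2],
       r2 = s$r.squared,
       fit = fit)
}

#' Stitch a serially diluted series back into one exponential
#'
#' Adds back ln(dilution factor) cumulatively at each dilution event so the
#' stitched log-series is continuous and a single growth rate can be
#' fitted across dilutions.
#'
#' @param timeH sampling times.
#' @param values measured values.
#' @param dilutionEvents data.frame(time_h, factor).
#' @return numeric vector of stitched (undiluted-equivalent) values.
#' @export
stitchDilutions <- function(timeH, values, dilutionEvents) {
  if (!nrow(dilutionEvents)) return(values)
  cumLog <- vapply(timeH, function(t)
    sum(log(dilutionEvents$factor[dilutionEvents$time_h <= t])), numeric(1))
  exp(log(values) + cumLog)
}

#' Verify steady-state (balanced) growth
#'
#' Balanced growth requires the biomass (OD600) and cell-number series to
#' grow exponentially at the same rate — parallel lines in a semi-log plot.
#' Both series are stitched across dilution events, fitted log-linearly,
#' and the culture passes iff (i) the curve spans at least
#' \code{minGenerations} generations, (ii) both fits are log-linear
#' (R^2 >= \code{r2Threshold}), and (iii) the two rates agree within
#' \code{tolerance}.
#'
#' @param curve a [GrowthCurve-class].
#' @param tolerance allowed |lambda_OD - lambda_count| (1/h), default 0.05.
#' @param r2Threshold log-linearity requirement, default 0.98.
#' @param minGenerations default 10.
#' @return list: \code{pass} (logical), \code{lambdaOd}, \code{lambdaCount},
#'   \code{generationsSpanned}, \code{reasons} (character, empty on pass).
#' @export
verifySteadyState <- function(curve, tolerance = 0.05, r2Threshold = 0.98,
                              minGenerations = 10) {
  stopifnot(is(curve, "GrowthCurve"))
  validObject(curve)
  od <- stitchDilutions(curve@timeH, curve@od600, curve@dilutionEvents)
  ct <- stitchDilutions(curve@timeH, curve@cellsPerMl, curve@dilutionEvents)
  fOd <- fitGrowthRate(curve@timeH, od)
  fCt <- fitGrowthRate(curve@timeH, ct)
  gens <- fOd$lambda * diff(range(curve@timeH)) / log(2)
  reasons <- character()
  if (gens < minGenerations)
    reasons <- c(reasons, sprintf(
      "culture spans %.1f generations (< %g required for steady state)",
      gens, minGenerations))
  if (fOd$r2 < r2Threshold || fCt$r2 < r2Threshold)
    reasons <- c(reasons, sprintf(
      "log-linearity violated (R2 OD %.3f, counts %.3f, need >= %.3f)",
      fOd$r2, fCt$r2, r2Threshold))
  if (abs(fOd$lambda - fCt$lambda) > tolerance)
    reasons <- c(reasons, sprintf(
      "biomass and cell-number rates differ: %.3f vs %.3f /h (tolerance %.3f)",
      fOd$lambda, fCt$lambda, tolerance))
  list(pass = length(reasons) == 0L, lambdaOd = fOd$lambda,
       lambdaCount = fCt$lambda, seOd = fOd$se, seCount = fCt$se,
       generationsSpanned = gens, reasons = reasons)
}

#' Simulate a serially diluted growth curve
#'
#' Generates paired OD600 and cell-concentration series growing at
#' \code{lambdaPerH} with multiplicative log-normal measurement noise,
#' diluted by \code{dilutionFactor} whenever OD exceeds \code{odCeiling}.
#' The defaults emulate a typical steady-state establishment protocol:
#' sampling every few minutes, dilution well inside the exponential regime,
#' and ~5e8 cells/mL per OD unit.
#'
#' @param lambdaPerH growth rate (1/h).
#' @param durationH total time (h); combined with lambda this sets the
#'   generations spanned.
#' @param dtH sampling interval (h), default 0.1.
#' @param od0 starting OD, default 0.02.
#' @param odCeiling dilution trigger, default 0.2.
#' @param dilutionFactor fold dilution, default 10.
#' @param cellsPerOdMl cells/mL per OD unit, default 5e8.
#' @param noiseCv measurement CV on both channels, default 0.02.
#' @param rngSeed integer seed.
#' @return a [GrowthCurve-class].
#' @export
simulateGrowthCurve <- function(lambdaPerH, durationH, dtH = 0.1, od0 = 0.02,
                                odCeiling = 0.2, dilutionFactor = 10,
                                cellsPerOdMl = 5e8, noiseCv = 0.02,
                                rngSeed = 1L) {
  stopifnot(lambdaPerH > 0, durationH > 0)
  times <- seq(0, durationH, by = dtH)
  n <- length(times)
  odTrue <- numeric(n)
  events <- data.frame(time_h = numeric(), factor = numeric())
  cur <- od0
  for (i in seq_len(n)) {
    if (i > 1L) cur <- cur * exp(lambdaPerH * dtH)
    if (cur > odCeiling) {
      cur <- cur / dilutionFactor
      events <- rbind(events,
                      data.frame(time_h = times[i], factor = dilutionFactor))
    }
    odTrue[i] <- cur
  }
  withSeed(rngSeed, {
    od <- odTrue * exp(rnorm(n, 0, noiseCv))
    ct <- odTrue * cellsPerOdMl * exp(rnorm(n, 0, noiseCv))
  })
  GrowthCurve(times, od, ct, events)
}

#' Population-averaged cell mass from OD and cell counts
#'
#' mbar = OD600 / (cells per mL), expressed in OD600·mL per 1e9 cells — an
#' intensive quantity, unchanged when both channels are scaled together.
#'
#' @param od600 optical density (positive).
#' @param cellsPerMl cell concentration (1/mL, positive).
#' @return mbar in OD600·mL per 1e9 cells.
#' @export
#' @examples
#' meanCellMass(0.2, 2e8) # 1
meanCellMass <- function(od600, cellsPerMl) {
  if (any(od600 <= 0)) stop("od600 must be positive")
  if (any(cellsPerMl <= 0)) stop("cellsPerMl must be positive")
  od600 / (cellsPerMl / 1e9)
}

#' Initiation mass
#'
#' m_i = (mass proxy) / (obar · ln 2): the cellular mass (or volume) per
#' replication origin at the moment of initiation, derived for a
#' steady-state population. The unit follows the mass proxy (µm^3 for cell
#' volume, OD600·mL per 1e9 cells for mbar; the latter equals
#' 10 x 10^-10 OD600·mL per cell).
#'
#' @param massProxy population-averaged volume Vbar or mass mbar (positive).
#' @param meanOrigins population-averaged oriC number obar (positive).
#' @return m_i in the units of \code{massProxy}.
#' @export
#' @examples
#' initiationMass(1, 1) # 1/ln 2
initiationMass <- function(massProxy, meanOrigins) {
  if (any(massProxy <= 0)) stop("massProxy must be positive")
  if (any(meanOrigins <= 0)) stop("meanOrigins must be positive")
  massProxy / meanOrigins / log(2)
}

#' Normalize a series by its cross-condition mean
#'
#' @param values numeric vector, length >= 2.
#' @return the relative series; always averages to exactly 1.
#' @export
#' @examples
#' relativeSeries(c(1, 3)) # 0.5, 1.5
relativeSeries <- function(values) {
  if (length(values) < 2L) stop("need at least 2 conditions")
  values / mean(values)
}

#' Classify the growth-rate trend of an initiation-mass series
#'
#' The series is "growth-rate-dependent" iff its largest pairwise percent
#' difference exceeds \code{thresholdPct} \emph{and} the series is monotone
#' when ordered by growth rate (ties broken toward "constant"); otherwise
#' "constant". The default threshold of 25% sits between the ~10%
#' variation read as consistent with a constant initiation mass and the
#' ~50% increase read as growth-rate dependence; it is configurable.
#'
#' @param mi initiation-mass values.
#' @param growthRates matching growth rates (1/h), distinct, length >= 2.
#' @param thresholdPct classification threshold, default 25.
#' @return list: \code{label}, \code{maxPairwisePct}, \code{monotone}.
#' @export
classifyTrend <- function(mi, growthRates, thresholdPct = 25) {
  if (length(mi) < 2L) stop("need at least 2 conditions")
  if (length(growthRates) != length(mi))
    stop("mi and growthRates must have equal length")
  if (anyDuplicated(growthRates))
    stop("growth rates must be distinct")
  ord <- order(growthRates)
  d <- diff(mi[ord])
  monotone <- all(d > 0) || all(d < 0)
  maxPct <- 100 * (max(mi) - min(mi)) / min(mi)
  label <- if (maxPct > thresholdPct && monotone) "growth-rate-dependent"
           else "constant"
  list(label = label, maxPairwisePct = maxPct, monotone = monotone)
}

#' Build an initiation-mass series across conditions
#'
#' Combines per-condition mass proxies and origin numbers into m_i values,
#' the relative (mean-normalized) series, and the trend classification.
#'
#' @param condition condition labels.
#' @param growthRatePerH growth rates (1/h).
#' @param massProxy Vbar (µm^3) or mbar (OD600·mL per 1e9 cells).
#' @param meanOrigins obar per condition.
#' @param thresholdPct trend threshold, default 25.
#' @return an [InitiationMassSeries-class].
#' @export
initiationMassSeries <- function(condition, growthRatePerH, massProxy,
                                 meanOrigins, thresholdPct = 25) {
  mi <- initiationMass(massProxy, meanOrigins)
  cls <- classifyTrend(mi, growthRatePerH, thresholdPct)
  tab <- data.frame(condition = condition,
                    growth_rate_per_h = growthRatePerH,
                    mass_proxy = massProxy, mean_origins = meanOrigins,
                    mi = mi, relative_mi = relativeSeries(mi),
                    stringsAsFactors = FALSE)
  new("InitiationMassSeries", table = tab, trendLabel = cls$label,
      maxPairwisePct = cls$maxPairwisePct, thresholdPct = thresholdPct)
}

#' Compare initiation-mass conclusions across analysis settings
#'
#' Takes per-setting, per-condition population summaries, builds an
#' initiation-mass series per setting, and flags a conflict when the trend
#' labels disagree — i.e. when the choice of software or parameter setting
#' flips the biological conclusion.
#'
#' @param summaries data.frame with columns \code{setting, condition,
#'   growth_rate_per_h, mass_proxy, mean_origins}; every setting must cover
#'   the same condition set.
#' @param thresholdPct trend threshold, default 25.
#' @return list: \code{series} (named list of
#'   [InitiationMassSeries-class]), \code{labels} (named character),
#'   \code{conflict} (logical), \code{report} (data.frame).
#' @export
compareSettings <- function(summaries, thresholdPct = 25) {
  need <- c("setting", "condition", "growth_rate_per_h", "mass_proxy",
            "mean_origins")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  settings <- unique(summaries$setting)
  if (length(settings) < 1L) stop("no settings supplied")
  condSets <- lapply(settings, function(s)
    sort(summaries$condition[summaries$setting == s]))
  if (length(unique(vapply(condSets, paste, character(1), collapse = "|"))) > 1L)
    stop("all settings must cover the same condition set")
  series <- lapply(settings, function(s) {
    sub <- summaries[summaries$setting == s, ]
    initiationMassSeries(sub$condition, sub$growth_rate_per_h,
                         sub$mass_proxy, sub$mean_origins, thresholdPct)
  })
  names(series) <- settings
  labels <- vapply(series, trendLabel, character(1))
  report <- do.call(rbind, lapply(settings, function(s) {
    tab <- resultTable(series[[s]])
    tab$setting <- s
    tab$trend <- labels[[s]]
    tab
  }))
  list(series = series, labels = labels,
       conflict = length(unique(labels)) > 1L, report = report)
}
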