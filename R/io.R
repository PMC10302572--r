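#' Bundled reference population size summaries
#'
#' Published population-averaged size parameters (mean +/- SD of length,
#' width, area, volume) for \emph{E. coli} K-12 NCM3722 grown in MOPS
#' medium with four carbon sources (glutamine, alanine, glycerol, glucose),
#' as quantified from the same phase-contrast images by six image-analysis
#' settings: MicrobeJ with auto-threshold offset -200 (\code{microbej_m200})
#' and 100 (\code{microbej_100}), Oufti with two cellwidth/meshwidth
#' parameter sets (\code{oufti_set1}, \code{oufti_set2}), BacStalk defaults
#' (\code{bacstalk}), and custom deep-learning scripts (\code{custom}).
#' These tables seed population models for the synthetic generator and the
#' settings-comparison workflow.
#'
#' @return long data.frame: \code{setting, condition, feature, mean, sd}
#'   (length/width in µm, area µm^2, volume µm^3).
#' @seealso [referenceGrowthRates()], [referenceModels()]
#' @export
referenceSizeSummaries <- function() {
  read.csv(system.file("extdata", "size_summaries.csv",
                       package = "bactomorph"),
           stringsAsFactors = FALSE)
}

#' Bundled reference growth rates per condition
#'
#' Steady-state growth rates of the four MOPS carbon-source conditions
#' accompanying [referenceSizeSummaries()].
#'
#' @return data.frame: \code{condition, growth_rate_per_h, growth_rate_sd}.
#' @export
referenceGrowthRates <- function() {
  read.csv(system.file("extdata", "growth_rates.csv",
                       package = "bactomorph"),
           stringsAsFactors = FALSE)
}

#' Population models seeded from the bundled reference summaries
#'
#' Builds one [PopulationModel-class] per condition from the length/width
#' means and SDs of the chosen analysis setting.
#'
#' @param setting one of the settings in [referenceSizeSummaries()];
#'   default \code{"custom"}.
#' @param lwCorrelation length-width correlation (not reported in summary
#'   tables), default 0.3.
#' @return named list of [PopulationModel-class], ordered by growth rate.
#' @export
#' @examples
#' names(referenceModels())
referenceModels <- function(setting = "custom", lwCorrelation = 0.3) {
  ss <- referenceSizeSummaries()
  gr <- referenceGrowthRates()
  ss <- ss[ss$setting == setting, ]
  if (!nrow(ss)) stop("unknown setting: ", setting)
  conds <- gr$condition[order(gr$growth_rate_per_h)]
  models <- lapply(conds, function(cond) {
    g <- function(feat, col) ss[[col]][ss$condition == cond & ss$feature == feat]
    PopulationModel(cond,
                    lengthMeanUm = g("length", "mean"),
                    lengthSdUm = g("length", "sd"),
                    widthMeanUm = g("width", "mean"),
                    widthSdUm = g("width", "sd"),
                    lwCorrelation = lwCorrelation,
                    growthRatePerH = gr$growth_rate_per_h[gr$condition == cond])
  })
  names(models) <- conds
  models
}

#' Write a typed CSV table
#'
#' CSV with header, UTF-8, '.' decimal separator. The schema (named
#' character vector column -> type, types "numeric"/"integer"/"character")
#' is checked before writing.
#'
#' @param rows data.frame.
#' @param path output file.
#' @param schema named character vector; names are required columns.
#' @return invisibly, \code{path}.
#' @export
writeSizeTable <- function(rows, path, schema) {
  checkSchema(rows, schema)
  write.csv(rows[names(schema)], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a typed CSV table
#'
#' @param path CSV file.
#' @param schema named character vector as in [writeSizeTable()].
#' @return validated data.frame with columns in schema order.
#' @export
readSizeTable <- function(path, schema) {
  rows <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  checkSchema(rows, schema)
  rows[names(schema)]
}

checkSchema <- function(rows, schema) {
  stopifnot(is.character(schema), !is.null(names(schema)))
  missing <- setdiff(names(schema), names(rows))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(rows)) stop("table has no rows")
  for (col in names(schema)) {
    ok <- switch(schema[[col]],
      numeric = is.numeric(rows[[col]]),
      integer = is.numeric(rows[[col]]) &&
        all(rows[[col]] == round(rows[[col]])),
      character = is.character(rows[[col]]) || is.factor(rows[[col]]),
      stop("unknown schema type: ", schema[[col]]))
    if (!ok)
      stop("column '", col, "' is not of type ", schema[[col]])
  }
  invisible(TRUE)
}

runConfigDefaults <- function() {
  list(
    seed = 1L,
    pixel_size_um = 0.065,
    setting = "custom",
    cells_per_condition = 100L,
    threshold_offset = 0,
    smoothing_sigma_px = 1,
    min_area_um2 = 0.3,
    max_area_um2 = 20,
    c_min = 40,
    d_min = 20,
    out_dir = ".",
    log_level = "info"
  )
}

#' Load and validate a run configuration from YAML
#'
#' Reads a YAML file describing one pipeline run (seed, pixel size, which
#' reference setting seeds the population models, segmentation parameters,
#' cell-cycle periods, output directory). Missing keys take documented
#' defaults; unknown keys are rejected with a field-level message.
#'
#' @param path YAML file.
#' @return validated named list of configuration values, plus
#'   \code{models} ([referenceModels()] for the chosen setting),
#'   \code{segmentation} (a [SegmentationConfig-class]) and
#'   \code{cellcycleFor} (function growth rate -> [CellCycleParams-class]).
#' @seealso [saveRunConfig()]
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- runConfigDefaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("field 'seed': must be a non-negative integer")
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    stop("field 'pixel_size_um': must be positive")
  if (!is.numeric(cfg$cells_per_condition) || cfg$cells_per_condition < 1)
    stop("field 'cells_per_condition': must be >= 1")
  if (cfg$min_area_um2 >= cfg$max_area_um2)
    stop("field 'min_area_um2': must be < max_area_um2")
  if (cfg$c_min <= 0 || cfg$d_min <= 0)
    stop("field 'c_min'/'d_min': must be positive")
  cfg$seed <- as.integer(cfg$seed)
  cfg$models <- referenceModels(cfg$setting)
  cfg$segmentation <- SegmentationConfig(
    thresholdOffset = cfg$threshold_offset,
    minAreaUm2 = cfg$min_area_um2, maxAreaUm2 = cfg$max_area_um2,
    smoothingSigmaPx = cfg$smoothing_sigma_px)
  cMin <- cfg$c_min; dMin <- cfg$d_min
  cfg$cellcycleFor <- function(lambdaPerH)
    paramsForGrowthRate(lambdaPerH, cMin, dMin)
  cfg
}

#' Save a run configuration as YAML
#'
#' Writes the scalar fields of a configuration (as returned by
#' [loadRunConfig()] or assembled by hand) so that a save/load round trip
#' reproduces the same configuration.
#'
#' @param config named list of configuration values.
#' @param path output YAML file.
#' @return invisibly, \code{path}.
#' @export
saveRunConfig <- function(config, path) {
  keep <- intersect(names(runConfigDefaults()), names(config))
  yaml::write_yaml(config[keep], path)
  invisible(path)
}
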