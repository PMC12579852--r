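## Table schemas, validation, CSV IO and the end-to-end pipeline driver.
## CSV dialect: UTF-8, comma separator, header row, '.' decimal, ISO dates,
## times as float seconds.

schemaDefs <- list(
  breath_events = list(
    required = c(whale = "character", sequence = "character",
                 start_s = "numeric", end_s = "numeric"),
    optional = c(breath = "numeric", class = "character",
                 naris_area_m2 = "numeric")),
  dives = list(
    required = c(whale = "character", start_s = "numeric", end_s = "numeric",
                 duration_s = "numeric", behavior = "character"),
    optional = c(dive_id = "character", tactic = "character",
                 bubble = "numeric", max_depth_m = "numeric")),
  depth_series = list(
    required = c(time_s = "numeric", depth_m = "numeric"),
    optional = c()),
  morph = list(
    required = c(whale = "character", tl_mean = "numeric", tl_sd = "numeric",
                 bai_mean = "numeric", bai_sd = "numeric"),
    optional = c(year = "numeric", bai_date = "character",
                 tl_true = "numeric", bai_true = "numeric")),
  gps_fixes = list(
    required = c(time_s = "numeric", lon = "numeric", lat = "numeric"),
    optional = c()),
  travel = list(
    required = c(whale = "character", swim_speed_mps = "numeric",
                 respiration_rate_bpm = "numeric"),
    optional = c(obs = "numeric")))

#' Table schemas used by the package
#'
#' @return named list of schemas; each has `required` and `optional` named
#'   character vectors mapping column names to semantic types.
#' @export
tableSchemas <- function() schemaDefs

#' Validate a table against a package schema
#'
#' Checks required columns, coercible types, and schema-specific invariants
#' (non-negative durations, breath end at or after start, monotone
#' timestamps for depth series). Errors are structured
#' (`whalebreath_validation_error`) and name the offending column or row.
#'
#' @param x a data.frame, or a path to a CSV file.
#' @param schema schema name, one of `names(tableSchemas())`.
#' @return the validated data.frame (invisibly typed), with attribute
#'   `validated_rows` set to the row count.
#' @examples
#' ev <- data.frame(whale = "W1", sequence = "S1", start_s = 0, end_s = 2)
#' validateTable(ev, "breath_events")
#' @export
validateTable <- function(x, schema) {
  wbAssert(schema %in% names(schemaDefs),
           paste("unknown schema:", schema))
  sc <- schemaDefs[[schema]]
  if (is.character(x) && length(x) == 1) {
    wbAssert(file.exists(x), paste("file not found:", x))
    x <- read.csv(x, stringsAsFactors = FALSE)
  }
  wbAssert(is.data.frame(x), "input must be a data.frame or CSV path")
  for (col in names(sc$required)) {
    if (!col %in% names(x))
      wbStop(sprintf("table '%s': missing required column '%s'", schema, col))
    type <- sc$required[[col]]
    if (type == "numeric") {
      v <- x[[col]]
      if (!is.numeric(v)) {
        suppressWarnings(v2 <- as.numeric(v))
        if (anyNA(v2) && !all(is.na(v)))
          wbStop(sprintf("table '%s': column '%s' is not numeric", schema, col))
        x[[col]] <- v2
      }
    } else {
      x[[col]] <- as.character(x[[col]])
    }
  }
  # schema-specific invariants
  if (schema == "breath_events" && nrow(x)) {
    bad <- which(x$end_s < x$start_s)
    if (length(bad))
      wbStop(sprintf("table 'breath_events': end_s < start_s at row %d", bad[1]))
  }
  if (schema == "dives" && nrow(x)) {
    bad <- which(x$duration_s <= 0)
    if (length(bad))
      wbStop(sprintf("table 'dives': non-positive duration_s at row %d", bad[1]))
    bad <- which(abs(x$end_s - x$start_s - x$duration_s) > 1e-6)
    if (length(bad))
      wbStop(sprintf("table 'dives': duration_s != end_s - start_s at row %d",
                     bad[1]))
  }
  if (schema == "depth_series" && nrow(x) > 1) {
    if (any(diff(x$time_s) <= 0))
      wbStop("table 'depth_series': time_s is not strictly increasing")
    if (any(x$depth_m < 0))
      wbStop("table 'depth_series': negative depth_m")
  }
  if (schema == "gps_fixes" && nrow(x) > 1) {
    if (any(diff(x$time_s) <= 0))
      wbStop("table 'gps_fixes': time_s is not strictly increasing")
  }
  attr(x, "validated_rows") <- nrow(x)
  x
}

#' Read and write package tables as CSV
#'
#' Thin wrappers around [validateTable()] and `write.csv` for the documented
#' table schemas.
#'
#' @param path CSV file path.
#' @param schema schema name (see [tableSchemas()]).
#' @param x data.frame to write.
#' @return `readTable` returns the validated data.frame; `writeTable` its
#'   path, invisibly.
#' @export
readTable <- function(path, schema) validateTable(path, schema)

#' @rdname readTable
#' @export
writeTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Convert a DepthSeries to/from its table form
#'
#' @param series a [DepthSeries-class]; `x` a depth table (`time_s`,
#'   `depth_m`) with uniform sampling.
#' @return `depthSeriesToTable` a data.frame; `tableToDepthSeries` a
#'   [DepthSeries-class].
#' @export
depthSeriesToTable <- function(series) {
  stopifnot(is(series, "DepthSeries"))
  data.frame(time_s = sampleTimes(series), depth_m = depths(series))
}

#' @rdname depthSeriesToTable
#' @export
tableToDepthSeries <- function(x) {
  x <- validateTable(x, "depth_series")
  dt <- diff(x$time_s)
  wbAssert(length(dt) >= 1, "depth table needs at least two samples")
  wbAssert(max(abs(dt - dt[1])) < 1e-6, "depth table is not uniformly sampled")
  depthSeries(x$depth_m, samplingRate = 1 / dt[1], startTime = x$time_s[1])
}

#' Run the full synthetic pipeline
#'
#' Executes simulate-data, compute-metrics, (optionally) model fitting, and
#' the FMR grid simulation, writing all artifacts as CSV/JSON under
#' `config$outDir`. Repeated runs with the same seed produce byte-identical
#' summary tables.
#'
#' @param config named list (or YAML path) with elements:
#'   `outDir`; `seed`; `nWhales`; `nSequencesPerWhale`;
#'   `fitModels` (logical, default FALSE) plus optional `mcmc` list
#'   (chains/iterations/warmup); `fmr` list passed to [fmrConfig()]
#'   (e.g. `iterations`); `logLevel` (`"info"` or `"quiet"`).
#' @return invisible list of artifact paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  wbAssert(is.list(config) && !is.null(config$outDir),
           "config must be a list (or YAML path) with an outDir")
  quiet <- identical(config$logLevel, "quiet")
  say <- function(...) if (!quiet) message("[whalebreath] ", ...)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  nW <- if (is.null(config$nWhales)) 10L else config$nWhales
  nS <- if (is.null(config$nSequencesPerWhale)) 5L else config$nSequencesPerWhale
  paths <- list()

  say("stage simulate-data: ", nW, " whales x ", nS, " sequences, seed ", seed)
  params <- truthParameters()
  whales <- generateWhales(nW, params, seed = seed)
  sim <- generateForagingData(whales, params, nS, seed = seed + 1)
  paths$whales <- file.path(config$outDir, "whales.csv")
  paths$events <- file.path(config$outDir, "breath_events.csv")
  paths$dives <- file.path(config$outDir, "dives.csv")
  writeTable(whales, paths$whales)
  writeTable(sim$events, paths$events)
  writeTable(sim$dives, paths$dives)

  say("stage compute-metrics")
  metrics <- sequenceMetrics(sim$events)
  paths$metrics <- file.path(config$outDir, "sequence_metrics.csv")
  writeTable(metrics, paths$metrics)

  if (isTRUE(config$fitModels)) {
    say("stage fit-model: recovery breath count")
    mc <- config$mcmc
    if (is.null(mc)) mc <- list(chains = 2, iterations = 2000, warmup = 500)
    ds <- buildDataset(modelDesign("recovery_breath_count"), metrics,
                       sim$dives, whales)
    fit <- fitRespirationModel(modelDesign("recovery_breath_count"), ds,
                               chains = mc$chains, iterations = mc$iterations,
                               warmup = mc$warmup, seed = seed + 2,
                               onFail = "warn")
    paths$coefficients <- file.path(config$outDir, "recovery_breath_count_summary.csv")
    writeTable(coefficientSummary(fit), paths$coefficients)
  }

  say("stage simulate-fmr")
  fmrArgs <- config$fmr
  if (is.null(fmrArgs)) fmrArgs <- list()
  fmrArgs$seed <- seed + 3
  cfg <- do.call(fmrConfig, fmrArgs)
  res <- runFMRGrid(cfg, recoveryCoefficients())
  paths$fmr_combos <- file.path(config$outDir, "fmr_combinations.csv")
  paths$fmr_comparisons <- file.path(config$outDir, "fmr_comparisons.csv")
  writeTable(comboSummary(res), paths$fmr_combos)
  writeTable(effectSizes(res), paths$fmr_comparisons)

  meta <- list(package_version = as.character(utils::packageVersion("whalebreath")),
               seed = seed,
               config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  paths$log <- file.path(config$outDir, "run_log.json")
  jsonlite::write_json(meta, paths$log, auto_unbox = TRUE)
  say("done: ", length(paths), " artifacts in ", config$outDir)
  invisible(paths)
}
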