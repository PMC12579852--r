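## Central S4 containers. Tabular inputs (breath events, dives, GPS fixes,
## morphometric estimates) stay plain data.frames with documented schemas
## (see validateTable); S4 is reserved for objects with real internal state.

#' Validation error constructor
#'
#' All input-validation failures in the package signal a condition of class
#' `whalebreath_validation_error`, so callers can distinguish bad inputs from
#' programming errors.
#'
#' @param msg message describing the failure, naming the offending column or
#'   row where applicable.
#' @param call. logical; include the call.
#' @keywords internal
#' @noRd
wbStop <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("whalebreath_validation_error", "error")))
}

wbAssert <- function(cond, msg) {
  if (!isTRUE(cond)) wbStop(msg)
  invisible(TRUE)
}

#' DepthSeries: a uniformly sampled depth record
#'
#' Container for a tag pressure-sensor depth trace, sampled at a fixed rate
#' with depth in metres, positive down.
#'
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot depth numeric vector of depths (m, >= 0).
#' @slot startTime epoch of the first sample (s).
#'
#' @seealso [depthSeries()], [findDives()], [countBreaths()]
#' @exportClass DepthSeries
setClass("DepthSeries",
  representation(samplingRate = "numeric", depth = "numeric",
                 startTime = "numeric"),
  prototype(samplingRate = 1, depth = numeric(0), startTime = 0)
)

setValidity("DepthSeries", function(object) {
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    return("samplingRate must be a single positive number (Hz)")
  if (length(object@depth) && any(!is.finite(object@depth)))
    return("depth contains non-finite values")
  if (length(object@depth) && any(object@depth < 0))
    return("depth must be >= 0 (metres, positive down)")
  if (length(object@startTime) != 1 || !is.finite(object@startTime))
    return("startTime must be a single finite number (s)")
  TRUE
})

#' Construct a DepthSeries
#'
#' @param depth numeric vector of depths (m, positive down).
#' @param samplingRate sampling rate (Hz).
#' @param startTime time of the first sample (s).
#' @return A [DepthSeries-class] object.
#' @examples
#' ds <- depthSeries(c(0, 0, 5, 5, 0), samplingRate = 1)
#' sampleTimes(ds)
#' @export
depthSeries <- function(depth, samplingRate = 1, startTime = 0) {
  wbAssert(length(depth) > 0, "depth series is empty")
  new("DepthSeries", samplingRate = samplingRate,
      depth = as.numeric(depth), startTime = startTime)
}

#' @describeIn depthSeries sampling rate accessor (Hz).
#' @param x a `DepthSeries`.
#' @export
samplingRate <- function(x) {
  stopifnot(is(x, "DepthSeries"))
  x@samplingRate
}

#' @describeIn depthSeries depth vector accessor (m).
#' @export
depths <- function(x) {
  stopifnot(is(x, "DepthSeries"))
  x@depth
}

#' @describeIn depthSeries sample timestamps (s from epoch).
#' @export
sampleTimes <- function(x) {
  stopifnot(is(x, "DepthSeries"))
  x@startTime + (seq_along(x@depth) - 1) / x@samplingRate
}

setMethod("show", "DepthSeries", function(object) {
  cat("DepthSeries:", length(object@depth), "samples @",
      object@samplingRate, "Hz (",
      round(length(object@depth) / object@samplingRate, 1), "s ), max depth",
      round(max(c(0, object@depth)), 2), "m\n")
})

#' ModelDesign: one respiration model specification
#'
#' Describes one row of the model family: which respiration metric is the
#' response, the error structure, which dive the behavioural covariates come
#' from (recovery = preceding dive, anticipation = following dive, combined =
#' both with tactic-matched sequences only, travel = travel observations),
#' and the fixed effects.
#'
#' @slot name design identifier, e.g. `"recovery_breath_count"`.
#' @slot response response column name in the metrics table.
#' @slot family `"poisson"` (log link) or `"gaussian_log"` (Gaussian on the
#'   natural-log response).
#' @slot timing `"recovery"`, `"anticipation"`, `"combined"` or `"travel"`.
#' @slot fixedEffects character vector of fixed-effect terms.
#' @slot randomEffect grouping factor for the random intercept.
#'
#' @seealso [modelDesign()], [buildDataset()], [fitRespirationModel()]
#' @exportClass ModelDesign
setClass("ModelDesign",
  representation(name = "character", response = "character",
                 family = "character", timing = "character",
                 fixedEffects = "character", randomEffect = "character"))

setValidity("ModelDesign", function(object) {
  if (!object@family %in% c("poisson", "gaussian_log"))
    return("family must be 'poisson' or 'gaussian_log'")
  if (!object@timing %in% c("recovery", "anticipation", "combined", "travel"))
    return("timing must be recovery, anticipation, combined or travel")
  TRUE
})

setMethod("show", "ModelDesign", function(object) {
  cat("ModelDesign '", object@name, "': ", object@response, " ~ ",
      paste(object@fixedEffects, collapse = " + "),
      " + (1 | ", object@randomEffect, ")\n  family: ", object@family,
      ", timing: ", object@timing, "\n", sep = "")
})

#' RespirationFit: a fitted Bayesian respiration model
#'
#' Holds posterior draws from a fitted mixed model together with the design,
#' the model-ready dataset, the standardization constants used for z-scoring
#' (required for later prediction), and convergence diagnostics.
#'
#' @slot design the [ModelDesign-class] that was fitted.
#' @slot draws matrix of posterior draws (rows = draws, named columns).
#' @slot mu matrix of per-observation linear-predictor draws (link scale).
#' @slot dataset the model-ready data.frame the model was fitted to.
#' @slot constants list of standardization constants: per continuous
#'   covariate a `c(mean, sd)` pair.
#' @slot diagnostics data.frame of per-parameter R-hat and effective sample
#'   size.
#' @slot truncated logical; Poisson family fitted with the zero-truncated
#'   likelihood.
#' @slot mcmc list of sampler settings (chains, iterations, warmup, seed).
#'
#' @seealso [fitRespirationModel()], [coefficientSummary()], [bayesR2()]
#' @exportClass RespirationFit
setClass("RespirationFit",
  representation(design = "ModelDesign", draws = "matrix", mu = "matrix",
                 dataset = "data.frame", constants = "list",
                 diagnostics = "data.frame", truncated = "logical",
                 mcmc = "list"))

#' Posterior draws of a fitted model
#'
#' @param object a [RespirationFit-class].
#' @return matrix of posterior draws (one column per monitored parameter).
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "RespirationFit", function(object) object@draws)

#' Standardization constants stored with a fit
#'
#' @param object a [RespirationFit-class].
#' @return named list of `c(mean, sd)` pairs used for z-scoring.
#' @export
setGeneric("standardization", function(object) standardGeneric("standardization"))

#' @rdname standardization
#' @export
setMethod("standardization", "RespirationFit", function(object) object@constants)

#' Convergence diagnostics of a fitted model
#'
#' @param object a [RespirationFit-class].
#' @return data.frame with columns `parameter`, `rhat`, `ess`.
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "RespirationFit", function(object) object@diagnostics)

setMethod("show", "RespirationFit", function(object) {
  cat("RespirationFit:", object@design@name, "(", object@design@family, ")\n")
  cat("  ", nrow(object@dataset), "observations,", nrow(object@draws),
      "posterior draws,", object@mcmc$chains, "chains\n")
  cat("  max R-hat:", round(max(object@diagnostics$rhat, na.rm = TRUE), 4),
      " min ESS:", round(min(object@diagnostics$ess, na.rm = TRUE)), "\n")
})

#' FMRConfig: constants and covariate grid for the daily FMR simulation
#'
#' All physiological constants, the daily activity budget, the travel
#' breath-hold/inhalation sampling distributions, the covariate grid, and the
#' Monte Carlo settings for [runFMRGrid()]. Defaults reproduce the study
#' conditions for PCFG gray whales.
#'
#' @slot H heat production per litre of O2 consumed (MJ/L).
#' @slot o2Mean,o2Sd mean and sd of the per-day O2 extraction fraction
#'   (truncated-normal on (0, 1)).
#' @slot budget named fractions of the day in `forage`, `search`, `travel`
#'   (sums to 1).
#' @slot travelHold,travelInhale lognormal `c(meanlog, sdlog)` for travel
#'   breath-hold and inhalation durations (s).
#' @slot preyEnergyDensity prey energy density (kJ/g).
#' @slot grid data.frame of covariate combinations (`TL`, `BAI`,
#'   `dive_duration`, `tactic`).
#' @slot iterations Monte Carlo iterations (simulated days) per combination.
#' @slot seed root RNG seed; each combination uses an independent substream.
#'
#' @seealso [fmrConfig()], [runFMRGrid()]
#' @exportClass FMRConfig
setClass("FMRConfig",
  representation(H = "numeric", o2Mean = "numeric", o2Sd = "numeric",
                 budget = "numeric", travelHold = "numeric",
                 travelInhale = "numeric", preyEnergyDensity = "numeric",
                 grid = "data.frame", iterations = "numeric",
                 seed = "numeric"))

setValidity("FMRConfig", function(object) {
  b <- object@budget
  if (length(b) != 3 || !all(c("forage", "search", "travel") %in% names(b)))
    return("budget must be named fractions: forage, search, travel")
  if (any(b <= 0) || any(b >= 1)) return("budget fractions must lie in (0, 1)")
  if (abs(sum(b) - 1) > 1e-9) return("budget fractions must sum to 1 (1e-9)")
  if (object@H <= 0) return("H must be > 0")
  if (object@o2Sd < 0) return("o2Sd must be >= 0")
  if (object@travelHold[2] < 0 || object@travelInhale[2] < 0)
    return("travel lognormal sdlog must be >= 0")
  if (object@preyEnergyDensity <= 0) return("preyEnergyDensity must be > 0")
  if (object@iterations < 1) return("iterations must be >= 1")
  need <- c("TL", "BAI", "dive_duration", "tactic")
  if (nrow(object@grid) && !all(need %in% names(object@grid)))
    return("grid must have columns TL, BAI, dive_duration, tactic")
  TRUE
})

setMethod("show", "FMRConfig", function(object) {
  cat("FMRConfig: H =", object@H, "MJ/L, O2 ~ N(", object@o2Mean, ",",
      object@o2Sd, ") truncated (0,1)\n")
  cat("  activity budget:", paste(names(object@budget), "=",
      object@budget, collapse = ", "), "\n")
  cat("  grid:", nrow(object@grid), "combinations x", object@iterations,
      "iterations, seed", object@seed, "\n")
})

#' FMRResult: per-combination FMR draws and effect-size comparisons
#'
#' @slot config the [FMRConfig-class] used.
#' @slot combos data.frame of per-combination summaries: mean daily FMR
#'   (MJ/day), central 95% interval, mean prey requirement (t/day) and its
#'   interval, mean daily inhalation time (s) and cycle counts.
#' @slot comparisons data.frame of comparison families: mean and sd of
#'   Cohen's d, of the FMR difference (MJ/day) and of the prey-requirement
#'   difference (t/day) across matched pairs.
#' @slot draws list of per-combination FMR draw vectors (empty unless
#'   `keepDraws = TRUE` in [runFMRGrid()]).
#'
#' @exportClass FMRResult
setClass("FMRResult",
  representation(config = "FMRConfig", combos = "data.frame",
                 comparisons = "data.frame", draws = "list"))

#' Per-combination FMR summaries
#' @param object an [FMRResult-class].
#' @return data.frame of per-combination summaries.
#' @export
setGeneric("comboSummary", function(object) standardGeneric("comboSummary"))

#' @rdname comboSummary
#' @export
setMethod("comboSummary", "FMRResult", function(object) object@combos)

#' Effect-size comparison table
#' @param object an [FMRResult-class].
#' @return data.frame of comparison families (Cohen's d, FMR and prey
#'   differences; mean and sd across matched pairs).
#' @export
setGeneric("effectSizes", function(object) standardGeneric("effectSizes"))

#' @rdname effectSizes
#' @export
setMethod("effectSizes", "FMRResult", function(object) object@comparisons)

setMethod("show", "FMRResult", function(object) {
  cat("FMRResult:", nrow(object@combos), "covariate combinations,",
      object@config@iterations, "iterations each\n")
  cat("  daily FMR range of means:",
      round(min(object@combos$fmr_mean), 1), "-",
      round(max(object@combos$fmr_mean), 1), "MJ/day\n")
  cat("  comparison families:",
      paste(object@comparisons$family, collapse = ", "), "\n")
})
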