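## Tag-style processing: dive detection, minimum breath counts, and travel
## series from depth time series and dive tables.

## maximal runs where cond is TRUE; returns start/end sample indices
runsWhere <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect dives in a depth series
#'
#' A dive is a maximal contiguous run of samples with depth greater than or
#' equal to `threshold`, lasting at least `minDuration` seconds. Crossings
#' are sample-aligned: a dive starts at the first sample at or below the
#' threshold depth and ends one sampling interval after the last such sample
#' (half-open convention), so the reported duration equals the number of
#' submerged samples times the sampling period.
#'
#' `minDepth` optionally discards runs whose maximum depth stays below a
#' floor; this separates whale-scale dives from the sub-metre submergences
#' that occur between breaths within a surface sequence.
#'
#' @param series a [DepthSeries-class].
#' @param threshold submergence threshold (m, > 0), default 0.2.
#' @param minDuration minimum dive duration (s), default 5 for whale-scale
#'   dives; use 0 for the within-surface micro-dive pass.
#' @param minDepth minimum maximum-depth of a run (m), default 0 (off).
#' @return data.frame with one row per dive: `start_s`, `end_s`,
#'   `duration_s`, `max_depth_m`.
#' @examples
#' ds <- depthSeries(rep(c(0, 5), each = 60), samplingRate = 1)
#' findDives(ds)
#' @export
findDives <- function(series, threshold = 0.2, minDuration = 5,
                      minDepth = 0) {
  stopifnot(is(series, "DepthSeries"))
  wbAssert(threshold > 0, "threshold must be > 0")
  wbAssert(length(series@depth) > 0, "depth series is empty")
  dt <- 1 / series@samplingRate
  runs <- runsWhere(series@depth >= threshold)
  if (!nrow(runs)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), max_depth_m = numeric(0)))
  }
  times <- sampleTimes(series)
  out <- data.frame(
    start_s = times[runs[, "start"]],
    end_s = times[runs[, "end"]] + dt,
    duration_s = (runs[, "end"] - runs[, "start"] + 1) * dt,
    max_depth_m = vapply(seq_len(nrow(runs)), function(i)
      max(series@depth[runs[i, "start"]:runs[i, "end"]]), numeric(1)))
  out <- out[out$duration_s >= minDuration & out$max_depth_m >= minDepth, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum breath count within a surface period
#'
#' Breaths appear in a depth record as brief surfacings (depth below
#' `threshold`) separated by very shallow submergences. Each surfacing
#' within the period counts as one breath; a surfacing longer than
#' `twoBreathCutoff` seconds is counted as (at least) two breaths and is
#' flagged, so the result is a minimum estimate.
#'
#' @param series a [DepthSeries-class].
#' @param startS,endS bounds of the surface period (s), typically the end of
#'   one detected dive and the start of the next.
#' @param threshold surfacing threshold (m), default 0.2.
#' @param twoBreathCutoff duration (s) above which a surfacing represents at
#'   least two breaths, default 10.
#' @return list with `count` (minimum breath count), `timestamps` (surfacing
#'   midpoints, s), `durations_s`, and `long` (logical flags for surfacings
#'   exceeding the cutoff).
#' @examples
#' d <- rep(0.05, 11); d[c(4, 8)] <- 0.5
#' s <- depthSeries(d, samplingRate = 1)
#' countBreaths(s, 0, 11)$count   # 3 surfacings
#' @export
countBreaths <- function(series, startS, endS, threshold = 0.2,
                         twoBreathCutoff = 10) {
  stopifnot(is(series, "DepthSeries"))
  wbAssert(endS >= startS, "surface period end precedes start")
  times <- sampleTimes(series)
  sel <- times >= startS & times < endS
  if (!any(sel)) {
    return(list(count = 0L, timestamps = numeric(0),
                durations_s = numeric(0), long = logical(0)))
  }
  d <- series@depth[sel]
  tt <- times[sel]
  dt <- 1 / series@samplingRate
  runs <- runsWhere(d < threshold)
  if (!nrow(runs)) {
    return(list(count = 0L, timestamps = numeric(0),
                durations_s = numeric(0), long = logical(0)))
  }
  dur <- (runs[, "end"] - runs[, "start"] + 1) * dt
  long <- dur > twoBreathCutoff
  list(count = as.integer(nrow(runs) + sum(long)),
       timestamps = (tt[runs[, "start"]] + tt[runs[, "end"]]) / 2,
       durations_s = dur, long = long)
}

#' Detect surface periods and breaths across a deployment
#'
#' Convenience wrapper: detects whale-scale dives, takes the gaps between
#' consecutive dives as surface periods, and applies [countBreaths()] to
#' each.
#'
#' @param series a [DepthSeries-class].
#' @param threshold submergence threshold (m), default 0.2.
#' @param minDuration minimum dive duration (s) for the dive pass.
#' @param minDepth minimum dive depth (m) separating whale-scale dives from
#'   between-breath submergences; default 1.
#' @param twoBreathCutoff see [countBreaths()].
#' @return data.frame with one row per surface period: `start_s`, `end_s`,
#'   `min_breath_count`, `n_long_surfacings`.
#' @export
detectBreaths <- function(series, threshold = 0.2, minDuration = 5,
                          minDepth = 1, twoBreathCutoff = 10) {
  dv <- findDives(series, threshold, minDuration, minDepth)
  if (nrow(dv) < 2) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      min_breath_count = integer(0),
                      n_long_surfacings = integer(0)))
  }
  out <- lapply(seq_len(nrow(dv) - 1), function(i) {
    cb <- countBreaths(series, dv$end_s[i], dv$start_s[i + 1], threshold,
                       twoBreathCutoff)
    data.frame(start_s = dv$end_s[i], end_s = dv$start_s[i + 1],
               min_breath_count = cb$count,
               n_long_surfacings = sum(cb$long))
  })
  do.call(rbind, out)
}

#' Group consecutive travel dives into travel series
#'
#' Maximal runs of `behavior == "travel"` in a time-ordered dive table share
#' a series id; any non-travel dive breaks the run. Non-travel dives get
#' `NA`.
#'
#' @param dives dive table with columns `start_s` and `behavior`, time
#'   ordered.
#' @return integer vector of series ids (NA for non-travel dives).
#' @examples
#' b <- c("travel", "travel", "forage", "travel")
#' groupTravelSeries(data.frame(start_s = 1:4, behavior = b))
#' @export
groupTravelSeries <- function(dives) {
  wbAssert(all(c("start_s", "behavior") %in% names(dives)),
           "dives needs columns start_s, behavior")
  if (is.unsorted(dives$start_s)) wbStop("dives must be time-ordered")
  isT <- dives$behavior == "travel"
  r <- rle(isT)
  ids <- integer(length(r$values))
  ids[r$values] <- seq_len(sum(r$values))
  out <- rep.int(ifelse(r$values, ids, NA_integer_), r$lengths)
  as.integer(out)
}

#' Travel respiration rate from tag travel series
#'
#' Pools minimum breath counts and series durations over all travel series:
#' 60 times the summed counts divided by the summed series seconds.
#'
#' @param breathCounts minimum breath count per travel series.
#' @param seriesDurationS duration (s) per travel series.
#' @return breaths per minute (0 when there are no series).
#' @examples
#' tagTravelRespirationRate(c(4, 6), c(120, 240))   # 60*10/360
#' @export
tagTravelRespirationRate <- function(breathCounts, seriesDurationS) {
  wbAssert(length(breathCounts) == length(seriesDurationS),
           "counts and durations differ in length")
  if (!length(breathCounts)) return(0)
  tot <- sum(seriesDurationS)
  wbAssert(tot > 0, "total travel series time must be > 0")
  60 * sum(breathCounts) / tot
}
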