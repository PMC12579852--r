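## Drone-derived respiration metrics computed from breath-event tables.
## Times are seconds from an arbitrary epoch; logs are natural logs.

#' Inhalation duration of a breath
#'
#' A recorded breath spans the exhalation and the immediately following
#' inhalation, which have equal durations in gray whales; the inhalation
#' duration is therefore one-half of the breath duration.
#'
#' @param start,end breath start and end times (s); vectorized.
#' @return inhalation duration(s) in seconds.
#' @examples
#' inhalationDuration(0, 2.4)   # 1.2
#' @export
inhalationDuration <- function(start, end) {
  wbAssert(length(start) == length(end), "start and end differ in length")
  if (any(end < start)) wbStop("breath end precedes start")
  (end - start) / 2
}

#' Summarize one surface sequence
#'
#' Computes the per-sequence respiration metrics from a time-ordered set of
#' breath events:
#' * sequence duration: start(terminal breath) - start(initial breath);
#' * breath count;
#' * total inhalation duration: sum of per-breath inhalation durations;
#' * mean inter-breath interval (IBI): mean of the end-to-start gaps between
#'   consecutive breaths (`NA` for single-breath sequences);
#' * inhalation accumulation rate: ordinary-least-squares slope of cumulative
#'   inhalation duration against time since the first breath's start, with a
#'   free intercept (`NA` for single-breath sequences);
#' * initial and terminal breath inhalation durations (terminal `NA` for a
#'   single breath).
#'
#' @param start,end numeric vectors of breath start/end times (s), in breath
#'   order.
#' @return one-row data.frame of metrics.
#' @examples
#' summarizeSequence(c(0, 20, 45), c(2, 22, 47))
#' @export
summarizeSequence <- function(start, end) {
  n <- length(start)
  wbAssert(n >= 1, "a surface sequence needs at least one breath")
  wbAssert(length(end) == n, "start and end differ in length")
  if (any(end < start)) wbStop("breath end precedes start")
  if (n >= 2) {
    if (any(diff(start) < 0)) wbStop("breaths are not time-ordered")
    if (any(start[-1] < end[-n])) wbStop("breaths overlap")
  }
  inh <- (end - start) / 2
  if (n >= 2) {
    gaps <- start[-1] - end[-n]
    x <- start - start[1]
    y <- cumsum(inh)
    sxx <- sum((x - mean(x))^2)
    slope <- if (sxx > 0) sum((x - mean(x)) * (y - mean(y))) / sxx else NA_real_
  } else {
    gaps <- NULL
    slope <- NA_real_
  }
  data.frame(
    n_breaths = n,
    sequence_duration_s = start[n] - start[1],
    total_inhalation_s = sum(inh),
    mean_ibi_s = if (n >= 2) mean(gaps) else NA_real_,
    accumulation_rate = slope,
    initial_inhalation_s = inh[1],
    terminal_inhalation_s = if (n >= 2) inh[n] else NA_real_)
}

#' Sequence-level metrics for a breath-event table
#'
#' Applies [summarizeSequence()] to every surface sequence in a breath-event
#' table and assigns breath classes (initial / middle / terminal; a
#' single-breath sequence is initial only).
#'
#' @param events breath-event data.frame with columns `whale`, `sequence`,
#'   `start_s`, `end_s`.
#' @return data.frame with one row per sequence: `whale`, `sequence` and the
#'   [summarizeSequence()] metrics, ordered by whale and first-breath time.
#' @examples
#' w <- generateWhales(2, seed = 1)
#' d <- generateForagingData(w, nSequencesPerWhale = 3, seed = 2)
#' head(sequenceMetrics(d$events))
#' @export
sequenceMetrics <- function(events) {
  events <- validateTable(events, "breath_events")
  out <- lapply(split(events, events$sequence), function(e) {
    e <- e[order(e$start_s), , drop = FALSE]
    cbind(data.frame(whale = e$whale[1], sequence = e$sequence[1],
                     first_breath_s = e$start_s[1], last_breath_s = e$end_s[nrow(e)],
                     stringsAsFactors = FALSE),
          summarizeSequence(e$start_s, e$end_s))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$whale, out$first_breath_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign breath classes within sequences
#'
#' @param events breath-event data.frame (`sequence`, `start_s`).
#' @return the table with a `class` column: the first breath of a sequence is
#'   `initial`, the last of a multi-breath sequence `terminal`, the rest
#'   `middle`; a single-breath sequence is `initial` only.
#' @export
classifyBreaths <- function(events) {
  events <- validateTable(events, "breath_events")
  events <- events[order(events$sequence, events$start_s), , drop = FALSE]
  events$class <- unlist(lapply(split(seq_len(nrow(events)), events$sequence),
                                function(i) breathClasses(length(i))),
                         use.names = FALSE)
  rownames(events) <- NULL
  events
}

#' Travel respiration rate
#'
#' Total breath count over an observation period divided by the total travel
#' duration, in breaths per minute.
#'
#' @param breathCount total number of breaths observed.
#' @param travelDurationS total travel duration (s, > 0).
#' @return breaths per minute.
#' @examples
#' travelRespirationRate(12, 600)   # 1.2
#' @export
travelRespirationRate <- function(breathCount, travelDurationS) {
  wbAssert(all(travelDurationS > 0), "travel duration must be > 0")
  wbAssert(all(breathCount >= 0), "breath count must be >= 0")
  60 * breathCount / travelDurationS
}

#' Mean swim speed from GPS fixes
#'
#' Sums great-circle (haversine) distances between consecutive fixes and
#' divides by the elapsed time, giving the mean ground speed over the
#' observation.
#'
#' @param fixes data.frame of time-ordered GPS fixes with columns `time_s`,
#'   `lon`, `lat` (>= 2 rows).
#' @return mean speed (m/s).
#' @examples
#' trk <- generateGpsTrack(60, speedMps = 2)
#' meanSwimSpeed(trk)
#' @export
meanSwimSpeed <- function(fixes) {
  fixes <- validateTable(fixes, "gps_fixes")
  wbAssert(nrow(fixes) >= 2, "need at least two GPS fixes")
  fixes <- fixes[order(fixes$time_s), , drop = FALSE]
  p <- as.matrix(fixes[, c("lon", "lat")])
  d <- geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                p[-1, , drop = FALSE])
  dt <- diff(fixes$time_s)
  wbAssert(all(dt > 0), "GPS fix times must be strictly increasing")
  sum(d) / sum(dt)
}

#' Match a body-condition measurement to an observation date
#'
#' Prefers a same-day body area index (BAI) measurement; otherwise the
#' nearest measurement within +/- `windowDays` days (ties broken toward the
#' earlier date); beyond the window, no match.
#'
#' @param observationDate a `Date`.
#' @param baiSeries data.frame with columns `bai_date`, `bai_mean`, `bai_sd`.
#' @param windowDays matching half-window (days), default 14.
#' @return the matched row of `baiSeries`, or `NULL` when no measurement
#'   falls inside the window.
#' @examples
#' s <- data.frame(bai_date = as.Date("2021-07-01") + c(0, 10),
#'                 bai_mean = c(25, 27), bai_sd = 1)
#' matchBai(as.Date("2021-07-04"), s)
#' @export
matchBai <- function(observationDate, baiSeries, windowDays = 14) {
  wbAssert(inherits(observationDate, "Date"), "observationDate must be a Date")
  wbAssert(all(c("bai_date", "bai_mean") %in% names(baiSeries)),
           "baiSeries needs columns bai_date, bai_mean")
  if (!nrow(baiSeries)) return(NULL)
  dd <- as.numeric(baiSeries$bai_date - observationDate)
  ok <- abs(dd) <= windowDays
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  # nearest; ties -> earlier date
  o <- order(abs(dd[cand]), dd[cand])
  baiSeries[cand[o[1]], , drop = FALSE]
}

#' Nares area standardized by body length
#'
#' Divides a measured nares area by the whale's total length so that nares
#' size can be compared across individuals of different size. The divisor
#' exponent is configurable (`power = 2` standardizes by TL^2).
#'
#' @param areaM2 nares area (m^2, >= 0).
#' @param tlM total length (m, > 0).
#' @param power exponent on TL in the divisor (default 1).
#' @return standardized area (m^2 / m^power).
#' @examples
#' standardizedNaresArea(0.003, 10)   # 3e-4
#' @export
standardizedNaresArea <- function(areaM2, tlM, power = 1) {
  wbAssert(all(areaM2 >= 0), "nares area must be >= 0")
  if (any(tlM <= 0)) wbStop("total length must be > 0")
  areaM2 / tlM^power
}
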