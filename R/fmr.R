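## Monte Carlo simulation of daily field metabolic rate (FMR), prey
## requirements and effect-size comparisons across a covariate grid.
##
## A simulated day is split by the activity budget into foraging time and
## travel/search time. Foraging time is filled with complete dive-recovery
## cycles (dive + breath-count x inter-breath interval + total inhalation
## duration); travel/search time with breath-hold + inhalation cycles drawn
## from the travel lognormals. The summed daily inhalation time converts to
## daily tidal volume, then FMR = H * %O2 * V_T(daily), then prey mass.

#' Default covariate grid for the FMR simulation
#'
#' Two total lengths (9 and 12 m), three body area index values (22, 27,
#' 32), three dive durations (60, 120, 300 s) and two foraging tactics
#' (headstand, forward swimming): 36 combinations.
#'
#' @return data.frame with columns `TL`, `BAI`, `dive_duration`, `tactic`.
#' @export
defaultFMRGrid <- function() {
  g <- expand.grid(TL = c(9, 12), BAI = c(22, 27, 32),
                   dive_duration = c(60, 120, 300),
                   tactic = c("headstand", "forward_swimming"),
                   stringsAsFactors = FALSE)
  g[order(g$TL, g$BAI, g$dive_duration, g$tactic), , drop = FALSE]
}

#' Default standardization constants for plug-in prediction
#'
#' Used when predicting respiration at grid combinations from bundled
#' coefficients rather than from a freshly fitted model: TL mean 10.5 m / sd
#' 1.5 m, BAI mean 27 / sd 5, dive duration mean 120 s / sd 120 s.
#'
#' @return named list of `c(mean, sd)` pairs.
#' @export
defaultPluginConstants <- function() {
  list(tl = c(mean = 10.5, sd = 1.5), bai = c(mean = 27, sd = 5),
       dive_duration = c(mean = 120, sd = 120))
}

#' Configuration for the daily FMR simulation
#'
#' @param H heat production per litre of O2 consumed (MJ/L), default 0.002.
#' @param o2Mean,o2Sd O2 extraction fraction distribution (default 0.11 and
#'   0.027; drawn once per simulated day from a normal truncated to (0, 1)).
#' @param budget daily activity fractions, default 36% foraging, 43%
#'   searching, 21% travelling (search and travel are pooled for sampling).
#' @param travelHold,travelInhale lognormal `c(meanlog, sdlog)` of travel
#'   breath-hold (3.66, 0.65) and inhalation (0.26, 0.17) durations, s.
#' @param preyEnergyDensity composite prey energy density, kJ/g (1.91).
#' @param grid covariate grid, default [defaultFMRGrid()].
#' @param iterations simulated days per combination (default 20,000).
#' @param seed root RNG seed; combinations use independent substreams.
#' @return an [FMRConfig-class].
#' @examples
#' fmrConfig(iterations = 100)
#' @export
fmrConfig <- function(H = 0.002, o2Mean = 0.11, o2Sd = 0.027,
                      budget = c(forage = 0.36, search = 0.43, travel = 0.21),
                      travelHold = c(meanlog = 3.66, sdlog = 0.65),
                      travelInhale = c(meanlog = 0.26, sdlog = 0.17),
                      preyEnergyDensity = 1.91,
                      grid = defaultFMRGrid(),
                      iterations = 20000, seed = 1) {
  new("FMRConfig", H = H, o2Mean = o2Mean, o2Sd = o2Sd,
      budget = unlist(budget)[c("forage", "search", "travel")],
      travelHold = unlist(travelHold), travelInhale = unlist(travelInhale),
      preyEnergyDensity = preyEnergyDensity,
      grid = as.data.frame(grid), iterations = iterations, seed = seed)
}

#' Daily tidal volume from summed inhalation time
#'
#' Tidal volume scales with inhalation duration and the square of body
#' length; summed over a day: `V = -7.24 + 2.14 * tIn * TL^2` (litres). The
#' negative intercept makes the formula nonphysical as `tIn` approaches
#' zero; realistic daily sums are thousands of seconds.
#'
#' @param tInDailyS summed daily inhalation duration (s, >= 0); vectorized.
#' @param tlM total length (m, > 0).
#' @return daily tidal volume (L).
#' @examples
#' tidalVolumeDaily(1, 12)   # 300.92
#' @export
tidalVolumeDaily <- function(tInDailyS, tlM) {
  if (any(tInDailyS < 0)) wbStop("tInDailyS must be >= 0")
  if (any(tlM <= 0)) wbStop("tlM must be > 0")
  -7.24 + 2.14 * tInDailyS * tlM^2
}

#' Daily field metabolic rate
#'
#' `FMR = H * %O2 * V_T(daily)` in MJ per day.
#'
#' @param H heat production per litre of O2 (MJ/L, >= 0).
#' @param o2Fraction O2 extraction fraction, in \[0, 1\].
#' @param vtDaily daily tidal volume (L).
#' @return FMR (MJ/day); vectorized.
#' @examples
#' fmrDaily(0.002, 0.11, 300.92)
#' @export
fmrDaily <- function(H, o2Fraction, vtDaily) {
  if (any(H < 0)) wbStop("H must be >= 0")
  if (any(o2Fraction < 0 | o2Fraction > 1))
    wbStop("o2Fraction must lie in [0, 1]")
  H * o2Fraction * vtDaily
}

#' Daily prey requirement
#'
#' Converts daily FMR to the prey mass supplying that energy:
#' `(FMR * 1000 kJ) / energy density` grams, reported in metric tons.
#'
#' @param fmrMj daily FMR (MJ, >= 0); vectorized.
#' @param energyDensity prey energy density (kJ/g, > 0), default 1.91.
#' @return prey mass (metric tons/day).
#' @examples
#' preyRequirement(191)   # 0.1 t
#' @export
preyRequirement <- function(fmrMj, energyDensity = 1.91) {
  if (any(energyDensity <= 0)) wbStop("energyDensity must be > 0")
  if (any(fmrMj < 0)) wbStop("fmrMj must be >= 0")
  fmrMj / (energyDensity * 1000)
}

#' Cohen's d between two draw vectors
#'
#' Standardized mean difference with the pooled sd
#' `sqrt((sd_a^2 + sd_b^2) / 2)`.
#'
#' @param a,b numeric draw vectors (>= 2 values each).
#' @return Cohen's d (scalar; positive when `a` has the larger mean).
#' @examples
#' cohensD(rnorm(100, 3), rnorm(100, 1))
#' @export
cohensD <- function(a, b) {
  wbAssert(length(a) >= 2 && length(b) >= 2, "need >= 2 draws per group")
  pooled <- sqrt((var(a) + var(b)) / 2)
  if (pooled == 0) wbStop("pooled sd is zero; Cohen's d undefined")
  (mean(a) - mean(b)) / pooled
}

## Fill a time budget with renewal cycles, vectorized over days.
## drawFun(m) returns list(len, tin) for m cycle draws (consumed day-major).
## The cycle that first reaches/exceeds the budget is included in full.
renewalFill <- function(n, budget, drawFun, expCycle, sdCycle) {
  if (budget <= 0) return(list(tin = rep(0, n), cycles = rep(0L, n)))
  outT <- numeric(n)
  outC <- integer(n)
  chunk <- 2500L
  done <- 0L
  while (done < n) {
    m <- as.integer(min(chunk, n - done))
    K <- max(2L, as.integer(ceiling(
      budget / expCycle + 10 * sqrt(budget / expCycle) * sdCycle / expCycle + 5)))
    repeat {
      d <- drawFun(m * K)
      csl <- cumsum(d$len)
      ends <- csl[seq(K, K * m, by = K)]
      cmat <- matrix(csl, K, m)
      cmat <- sweep(cmat, 2, c(0, ends[-m]))
      kx <- as.integer(colSums(cmat < budget)) + 1L
      if (max(kx) <= K) {
        cst <- cumsum(d$tin)
        endsT <- cst[seq(K, K * m, by = K)]
        ctm <- sweep(matrix(cst, K, m), 2, c(0, endsT[-m]))
        sel <- kx + (seq_len(m) - 1L) * K
        outT[done + seq_len(m)] <- ctm[sel]
        outC[done + seq_len(m)] <- kx
        break
      }
      K <- as.integer(ceiling(K * 1.5))
    }
    done <- done + m
  }
  list(tin = outT, cycles = outC)
}

## lognormal moments
lnMean <- function(ml, sl) exp(ml + sl^2 / 2)
lnVar <- function(ml, sl) (exp(sl^2) - 1) * lnMean(ml, sl)^2

#' Simulate foraging dive-recovery cycles over a time budget
#'
#' Each cycle is one dive plus its recovery surfacing: the dive duration,
#' a breath count drawn zero-truncated Poisson with mean `countMean` (or
#' fixed at `countFixed`), that many inter-breath intervals at one lognormal
#' IBI draw, and one lognormal total-inhalation draw. Cycles accumulate
#' until the cumulative cycle time first reaches or exceeds the budget; the
#' crossing cycle counts in full.
#'
#' @param countMean Poisson mean of the breath count (> 0); the realized
#'   count is truncated at >= 1.
#' @param countFixed optional fixed breath count overriding the Poisson
#'   draw (degenerate limit).
#' @param ibiMeanlog,ibiSdlog lognormal parameters of the per-cycle IBI (s).
#' @param tinMeanlog,tinSdlog lognormal parameters of the per-cycle total
#'   inhalation duration (s).
#' @param diveDurationS dive duration per cycle (s).
#' @param budgetS foraging time budget (s, >= 0).
#' @param n number of independent periods (days) to simulate.
#' @return list with `tin` (summed inhalation time per period, s) and
#'   `cycles` (completed cycle count per period).
#' @examples
#' simulateForagingPeriod(countFixed = 2, ibiMeanlog = log(14),
#'                        tinMeanlog = log(2.75), diveDurationS = 60,
#'                        budgetS = 31104)
#' @export
simulateForagingPeriod <- function(countMean = NULL, countFixed = NULL,
                                   ibiMeanlog, ibiSdlog = 0,
                                   tinMeanlog, tinSdlog = 0,
                                   diveDurationS, budgetS, n = 1) {
  wbAssert(budgetS >= 0, "budgetS must be >= 0")
  wbAssert(!is.null(countMean) || !is.null(countFixed),
           "either countMean or countFixed is required")
  if (is.null(countFixed)) wbAssert(countMean > 0, "countMean must be > 0")
  en <- if (!is.null(countFixed)) countFixed else ztpMean(countMean)
  vn <- if (!is.null(countFixed)) 0 else ztpVar(countMean)
  mIbi <- lnMean(ibiMeanlog, ibiSdlog)
  mTin <- lnMean(tinMeanlog, tinSdlog)
  expCycle <- diveDurationS + en * mIbi + mTin
  sdCycle <- sqrt(vn * mIbi^2 + en^2 * lnVar(ibiMeanlog, ibiSdlog) +
                  lnVar(tinMeanlog, tinSdlog))
  drawFun <- function(m) {
    N <- if (!is.null(countFixed)) rep(countFixed, m) else rztpois(m, countMean)
    ibi <- if (ibiSdlog > 0) rlnorm(m, ibiMeanlog, ibiSdlog)
           else rep(exp(ibiMeanlog), m)
    tin <- if (tinSdlog > 0) rlnorm(m, tinMeanlog, tinSdlog)
           else rep(exp(tinMeanlog), m)
    list(len = diveDurationS + N * ibi + tin, tin = tin)
  }
  renewalFill(n, budgetS, drawFun, expCycle, sdCycle)
}

#' Simulate travel/search breathing over a time budget
#'
#' Alternates lognormal breath-hold and inhalation draws, accumulating both
#' into elapsed time until it first reaches or exceeds the budget, and
#' returns the summed inhalation time.
#'
#' @param holdMeanlog,holdSdlog breath-hold lognormal parameters (defaults
#'   3.66, 0.65; s).
#' @param inhaleMeanlog,inhaleSdlog inhalation lognormal parameters
#'   (defaults 0.26, 0.17; s).
#' @param budgetS travel/search time budget (s, >= 0).
#' @param n number of independent periods to simulate.
#' @return list with `tin` (summed inhalation time per period, s) and
#'   `cycles`.
#' @examples
#' simulateTravelPeriod(budgetS = 3600)
#' @export
simulateTravelPeriod <- function(holdMeanlog = 3.66, holdSdlog = 0.65,
                                 inhaleMeanlog = 0.26, inhaleSdlog = 0.17,
                                 budgetS, n = 1) {
  wbAssert(budgetS >= 0, "budgetS must be >= 0")
  mh <- lnMean(holdMeanlog, holdSdlog)
  mi <- lnMean(inhaleMeanlog, inhaleSdlog)
  expCycle <- mh + mi
  sdCycle <- sqrt(lnVar(holdMeanlog, holdSdlog) +
                  lnVar(inhaleMeanlog, inhaleSdlog))
  drawFun <- function(m) {
    hold <- if (holdSdlog > 0) rlnorm(m, holdMeanlog, holdSdlog)
            else rep(exp(holdMeanlog), m)
    inh <- if (inhaleSdlog > 0) rlnorm(m, inhaleMeanlog, inhaleSdlog)
           else rep(exp(inhaleMeanlog), m)
    list(len = hold + inh, tin = inh)
  }
  renewalFill(n, budgetS, drawFun, expCycle, sdCycle)
}

#' Simulate daily FMR at one covariate combination
#'
#' Splits the day by the activity budget (foraging vs pooled travel/search),
#' fills each part with [simulateForagingPeriod()] and
#' [simulateTravelPeriod()] cycles, draws one O2 extraction fraction per day
#' from the truncated normal, and converts the summed daily inhalation time
#' through daily tidal volume to FMR and prey mass.
#'
#' @param combo list/row with `TL` (m) (other covariates act through
#'   `predictions`).
#' @param predictions list with elements `count` (`$mean`, or `$fixed` for
#'   the degenerate limit), `ibi` and `tin` (`$meanlog`, `$sdlog`), e.g.
#'   from [predictResponse()].
#' @param config an [FMRConfig-class].
#' @param n simulated days.
#' @return data.frame: `fmr_mj`, `prey_t`, `t_in_daily_s`,
#'   `foraging_cycles`.
#' @export
simulateDay <- function(combo, predictions, config = fmrConfig(), n = 1) {
  stopifnot(is(config, "FMRConfig"))
  wbAssert(all(c("count", "ibi", "tin") %in% names(predictions)),
           "predictions must supply count, ibi and tin")
  wbAssert((!is.null(predictions$count$mean) ||
              !is.null(predictions$count$fixed)) &&
             !is.null(predictions$ibi$meanlog) &&
             !is.null(predictions$tin$meanlog),
           "predictions are incomplete (need count$mean, ibi$meanlog, tin$meanlog)")
  day <- 86400
  fBudget <- day * config@budget[["forage"]]
  tBudget <- day * (config@budget[["search"]] + config@budget[["travel"]])
  sdl <- function(x) if (is.null(x$sdlog)) 0 else x$sdlog
  fg <- simulateForagingPeriod(
    countMean = predictions$count$mean,
    countFixed = predictions$count$fixed,
    ibiMeanlog = predictions$ibi$meanlog, ibiSdlog = sdl(predictions$ibi),
    tinMeanlog = predictions$tin$meanlog, tinSdlog = sdl(predictions$tin),
    diveDurationS = combo$dive_duration, budgetS = fBudget, n = n)
  tr <- simulateTravelPeriod(
    holdMeanlog = config@travelHold[["meanlog"]],
    holdSdlog = config@travelHold[["sdlog"]],
    inhaleMeanlog = config@travelInhale[["meanlog"]],
    inhaleSdlog = config@travelInhale[["sdlog"]],
    budgetS = tBudget, n = n)
  o2 <- rtruncnorm(n, config@o2Mean, config@o2Sd, lower = 0, upper = 1)
  tin <- fg$tin + tr$tin
  vt <- tidalVolumeDaily(tin, combo$TL)
  fmr <- fmrDaily(config@H, o2, vt)
  data.frame(fmr_mj = fmr, prey_t = preyRequirement(fmr, config@preyEnergyDensity),
             t_in_daily_s = tin, foraging_cycles = fg$cycles)
}

## per-combination substream seed derived from the root seed
comboSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647)
}

## comparison families: variable, larger level, smaller level
comparisonFamilies <- function() {
  list(
    list(family = "TL_12_9", var = "TL", hi = 12, lo = 9),
    list(family = "BAI_27_22", var = "BAI", hi = 27, lo = 22),
    list(family = "BAI_32_22", var = "BAI", hi = 32, lo = 22),
    list(family = "BAI_32_27", var = "BAI", hi = 32, lo = 27),
    list(family = "dive_120_300", var = "dive_duration", hi = 120, lo = 300),
    list(family = "dive_60_120", var = "dive_duration", hi = 60, lo = 120),
    list(family = "dive_60_300", var = "dive_duration", hi = 60, lo = 300),
    list(family = "tactic_headstand_forward", var = "tactic",
         hi = "headstand", lo = "forward_swimming"))
}

#' Run the daily FMR Monte Carlo over the covariate grid
#'
#' For every grid combination, predicts breath count, mean IBI and total
#' inhalation duration (plug-in coefficients unless per-combination
#' predictions are supplied), simulates `iterations` days with
#' [simulateDay()] under an independent RNG substream, and summarizes FMR
#' and prey draws. For each comparison family (TL 12 vs 9; BAI 27-22,
#' 32-22, 32-27; dive 120-300, 60-120, 60-300; headstand vs forward
#' swimming) Cohen's d and the FMR/prey differences are computed over every
#' matched pair of combinations differing only in that variable, and
#' reported as mean and sd across pairs.
#'
#' @param config an [FMRConfig-class].
#' @param coefficients data.frame like [recoveryCoefficients()] (columns
#'   `term`, `breath_count`, `total_inhalation`, `ibi`).
#' @param constants standardization constants for the plug-in prediction,
#'   default [defaultPluginConstants()].
#' @param predictions optional list (length `nrow(grid)`) of prediction
#'   lists overriding the plug-in route.
#' @param sdlogs optional named numeric `c(ibi = , tin = )` residual sds on
#'   the log scale for sampling the lognormal responses (default 0: point
#'   predictions at the posterior means).
#' @param keepDraws keep per-combination FMR draws in the result.
#' @return an [FMRResult-class].
#' @examples
#' cfg <- fmrConfig(iterations = 200, seed = 7)
#' res <- runFMRGrid(cfg)
#' effectSizes(res)
#' @export
runFMRGrid <- function(config = fmrConfig(), coefficients = recoveryCoefficients(),
                       constants = defaultPluginConstants(),
                       predictions = NULL, sdlogs = c(ibi = 0, tin = 0),
                       keepDraws = FALSE) {
  stopifnot(is(config, "FMRConfig"))
  grid <- config@grid
  wbAssert(nrow(grid) >= 1, "empty covariate grid")
  if (!is.null(predictions))
    wbAssert(length(predictions) == nrow(grid),
             "predictions must match the grid (one element per combination)")

  if (is.null(predictions)) {
    cf <- function(col) setNames(coefficients[[col]], coefficients$term)
    predictions <- lapply(seq_len(nrow(grid)), function(i) {
      cb <- as.list(grid[i, ])
      cb$bubble <- 0
      list(count = predictResponse(cf("breath_count"), cb, constants,
                                   family = "poisson"),
           ibi = predictResponse(cf("ibi"), cb, constants,
                                 family = "gaussian_log",
                                 sdlog = unname(sdlogs[["ibi"]])),
           tin = predictResponse(cf("total_inhalation"), cb, constants,
                                 family = "gaussian_log",
                                 sdlog = unname(sdlogs[["tin"]])))
    })
  }

  draws <- vector("list", nrow(grid))
  combos <- grid
  for (i in seq_len(nrow(grid))) {
    set.seed(comboSeed(config@seed, i))
    sim <- simulateDay(as.list(grid[i, ]), predictions[[i]], config,
                       n = config@iterations)
    draws[[i]] <- sim
    q <- quantile(sim$fmr_mj, c(0.025, 0.975))
    qp <- quantile(sim$prey_t, c(0.025, 0.975))
    combos$fmr_mean[i] <- mean(sim$fmr_mj)
    combos$fmr_lower95[i] <- unname(q[1])
    combos$fmr_upper95[i] <- unname(q[2])
    combos$prey_mean[i] <- mean(sim$prey_t)
    combos$prey_lower95[i] <- unname(qp[1])
    combos$prey_upper95[i] <- unname(qp[2])
    combos$t_in_daily_mean_s[i] <- mean(sim$t_in_daily_s)
    combos$foraging_cycles_mean[i] <- mean(sim$foraging_cycles)
  }

  others <- c("TL", "BAI", "dive_duration", "tactic")
  comp <- lapply(comparisonFamilies(), function(fm) {
    keys <- setdiff(others, fm$var)
    hiIdx <- which(grid[[fm$var]] == fm$hi)
    dvals <- fdiff <- pdiff <- numeric(0)
    for (i in hiIdx) {
      match <- rep(grid[[fm$var]] == fm$lo, 1)
      for (k in keys) match <- match & grid[[k]] == grid[[k]][i]
      j <- which(match)
      if (length(j) != 1) next
      dvals <- c(dvals, cohensD(draws[[i]]$fmr_mj, draws[[j]]$fmr_mj))
      fdiff <- c(fdiff, mean(draws[[i]]$fmr_mj) - mean(draws[[j]]$fmr_mj))
      pdiff <- c(pdiff, mean(draws[[i]]$prey_t) - mean(draws[[j]]$prey_t))
    }
    data.frame(family = fm$family, n_pairs = length(dvals),
               d_mean = mean(dvals), d_sd = sd(dvals),
               fmr_diff_mean = mean(fdiff), fmr_diff_sd = sd(fdiff),
               prey_diff_mean = mean(pdiff), prey_diff_sd = sd(pdiff))
  })
  comp <- do.call(rbind, comp)
  rownames(combos) <- rownames(comp) <- NULL
  new("FMRResult", config = config, combos = combos, comparisons = comp,
      draws = if (keepDraws) lapply(draws, `[[`, "fmr_mj") else list())
}
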