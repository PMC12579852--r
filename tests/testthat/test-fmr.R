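test_that("daily tidal volume follows the length-squared inhalation formula", {
  expect_equal(tidalVolumeDaily(1, 12), 300.92)
  expect_equal(tidalVolumeDaily(1000, 9), 173332.76)
  expect_equal(tidalVolumeDaily(0, 10), -7.24)   # nonphysical intercept
  expect_error(tidalVolumeDaily(-1, 10), class = "whalebreath_validation_error")
  expect_error(tidalVolumeDaily(1, 0), class = "whalebreath_validation_error")
})

test_that("daily FMR multiplies heat, extraction and tidal volume", {
  expect_equal(fmrDaily(0.002, 0.11, 300.92), 0.0662024)
  expect_equal(fmrDaily(0.002, 0.11, 0), 0)
  expect_equal(fmrDaily(0.004, 0.11, 300.92), 2 * fmrDaily(0.002, 0.11, 300.92))
  expect_error(fmrDaily(0.002, 1.2, 10), class = "whalebreath_validation_error")
})

test_that("prey requirements convert megajoules to metric tons", {
  expect_equal(preyRequirement(191, 1.91), 0.1)
  expect_equal(preyRequirement(0), 0)
  expect_equal(preyRequirement(200), 2 * preyRequirement(100))
  expect_error(preyRequirement(10, 0), class = "whalebreath_validation_error")
})

test_that("Cohen's d matches its closed form and is antisymmetric", {
  x <- rnorm(50)
  expect_equal(cohensD(x, x), 0)
  expect_equal(cohensD(c(2, 3, 4), c(0, 1, 2)), 2)   # means 3,1; sds 1,1
  a <- rnorm(50, 1); b <- rnorm(50, 0)
  expect_equal(cohensD(a, b), -cohensD(b, a))
  expect_error(cohensD(c(1, 1), c(1, 1)), class = "whalebreath_validation_error")
})

test_that("degenerate foraging cycles fill the budget in closed form", {
  # fixed count 2, IBI 14 s, total inhalation 2.75 s, dive 60 s:
  # cycle 90.75 s; 31,104 s budget -> ceil = 343 cycles, 943.25 s inhaled
  f <- simulateForagingPeriod(countFixed = 2, ibiMeanlog = log(14),
                              tinMeanlog = log(2.75), diveDurationS = 60,
                              budgetS = 31104)
  expect_identical(f$cycles, 343L)
  expect_equal(f$tin, 343 * 2.75)
  z <- simulateForagingPeriod(countFixed = 2, ibiMeanlog = log(14),
                              tinMeanlog = log(2.75), diveDurationS = 60,
                              budgetS = 0)
  expect_identical(z$cycles, 0L)
  expect_equal(z$tin, 0)
  expect_error(simulateForagingPeriod(countMean = 0, ibiMeanlog = 1,
                                      tinMeanlog = 1, diveDurationS = 60,
                                      budgetS = 100),
               class = "whalebreath_validation_error")
})

test_that("stochastic cycle counts follow the renewal approximation", {
  set.seed(161)
  lam <- 2.2; ibiM <- log(14); tinM <- log(2.75)
  f <- simulateForagingPeriod(countMean = lam, ibiMeanlog = ibiM,
                              ibiSdlog = 0.2, tinMeanlog = tinM,
                              tinSdlog = 0.2, diveDurationS = 120,
                              budgetS = 31104, n = 500)
  en <- ztpoisMean(lam)
  expCycle <- 120 + en * exp(ibiM + 0.02) + exp(tinM + 0.02)
  expect_equal(mean(f$cycles), 31104 / expCycle, tolerance = 0.02)
})

test_that("degenerate travel cycles fill the budget in closed form", {
  tr <- simulateTravelPeriod(holdMeanlog = log(40), holdSdlog = 0,
                             inhaleMeanlog = log(1.2), inhaleSdlog = 0,
                             budgetS = 55296)
  expect_identical(tr$cycles, as.integer(ceiling(55296 / 41.2)))
  expect_equal(tr$tin, ceiling(55296 / 41.2) * 1.2, tolerance = 1e-9)
  z <- simulateTravelPeriod(budgetS = 0)
  expect_equal(z$tin, 0)
})

test_that("travel sampling reproduces the lognormal moments", {
  set.seed(171)
  meanHold <- exp(3.66 + 0.65^2 / 2)     # ~48.03 s
  meanInh <- exp(0.26 + 0.17^2 / 2)      # ~1.316 s
  budget <- (meanHold + meanInh) * 10000 # ~10,000 cycles
  tr <- simulateTravelPeriod(budgetS = budget)
  expect_gt(tr$cycles, 9000)
  seInh <- sqrt((exp(0.17^2) - 1)) * meanInh / sqrt(tr$cycles)
  expect_equal(tr$tin / tr$cycles, meanInh, tolerance = 3 * seInh / meanInh)
  sdHold <- sqrt(exp(0.65^2) - 1) * meanHold
  seCyc <- sdHold / sqrt(tr$cycles)
  expect_equal(budget / tr$cycles, meanHold + meanInh,
               tolerance = 3 * seCyc / (meanHold + meanInh))
})

test_that("a fully degenerate day reproduces the hand-computed FMR chain", {
  cfg <- fmrConfig(o2Sd = 0,
                   travelHold = c(meanlog = log(40), sdlog = 0),
                   travelInhale = c(meanlog = log(1.2), sdlog = 0),
                   iterations = 1)
  preds <- list(count = list(fixed = 2),
                ibi = list(meanlog = log(14), sdlog = 0),
                tin = list(meanlog = log(2.75), sdlog = 0))
  day <- simulateDay(list(TL = 12, dive_duration = 60), preds, cfg, n = 3)
  tinF <- 343 * 2.75
  tinT <- ceiling(55296 / 41.2) * 1.2
  vt <- -7.24 + 2.14 * (tinF + tinT) * 144
  fmr <- 0.002 * 0.11 * vt
  expect_equal(day$t_in_daily_s, rep(tinF + tinT, 3), tolerance = 1e-9)
  expect_equal(day$fmr_mj, rep(fmr, 3), tolerance = 1e-9)
  expect_equal(day$prey_t, rep(fmr / 1910, 3), tolerance = 1e-9)
  expect_equal(day$foraging_cycles, rep(343L, 3))

  # with O2 sd 0 and all distributions degenerate, FMR has no variance
  expect_equal(var(day$fmr_mj), 0)
  # FMR strictly increases in TL at fixed respiration predictions
  day9 <- simulateDay(list(TL = 9, dive_duration = 60), preds, cfg, n = 1)
  expect_gt(day$fmr_mj[1], day9$fmr_mj[1])
})

test_that("the covariate grid has 36 combinations and the matched-pair counts", {
  g <- defaultFMRGrid()
  expect_equal(nrow(g), 36)
  expect_equal(nrow(unique(g)), 36)
  cfg <- fmrConfig(iterations = 50, seed = 5)
  res <- runFMRGrid(cfg, keepDraws = TRUE)
  es <- effectSizes(res)
  expect_equal(es$n_pairs[es$family == "TL_12_9"], 18)
  expect_equal(es$n_pairs[es$family == "tactic_headstand_forward"], 18)
  expect_equal(es$n_pairs[es$family == "BAI_32_22"], 12)
  expect_equal(es$n_pairs[es$family == "dive_60_300"], 12)
})

test_that("family effect sizes equal brute-force pairwise enumeration", {
  cfg <- fmrConfig(iterations = 80, seed = 9)
  res <- runFMRGrid(cfg, keepDraws = TRUE)
  g <- comboSummary(res)
  dr <- res@draws
  # brute force: average d over all pairs differing only in TL
  ds <- c()
  for (i in which(g$TL == 12)) {
    j <- which(g$TL == 9 & g$BAI == g$BAI[i] &
                 g$dive_duration == g$dive_duration[i] &
                 g$tactic == g$tactic[i])
    ds <- c(ds, cohensD(dr[[i]], dr[[j]]))
  }
  es <- effectSizes(res)
  expect_equal(es$d_mean[es$family == "TL_12_9"], mean(ds), tolerance = 1e-12)
  expect_equal(es$d_sd[es$family == "TL_12_9"], sd(ds), tolerance = 1e-12)
})

test_that("effect sizes are invariant to the heat-production constant", {
  r1 <- runFMRGrid(fmrConfig(iterations = 150, seed = 12))
  r2 <- runFMRGrid(fmrConfig(H = 0.02, iterations = 150, seed = 12))
  expect_equal(effectSizes(r1)$d_mean, effectSizes(r2)$d_mean,
               tolerance = 1e-12)
  expect_equal(effectSizes(r2)$fmr_diff_mean,
               10 * effectSizes(r1)$fmr_diff_mean, tolerance = 1e-9)
})

test_that("grid runs are reproducible by seed", {
  a <- runFMRGrid(fmrConfig(iterations = 60, seed = 4), keepDraws = TRUE)
  b <- runFMRGrid(fmrConfig(iterations = 60, seed = 4), keepDraws = TRUE)
  expect_identical(comboSummary(a), comboSummary(b))
  expect_identical(a@draws, b@draws)
  c <- runFMRGrid(fmrConfig(iterations = 60, seed = 5))
  expect_false(identical(comboSummary(a)$fmr_mean, comboSummary(c)$fmr_mean))
})
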