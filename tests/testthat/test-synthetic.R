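test_that("generation is reproducible for a fixed seed", {
  p <- truthParameters()
  expect_identical(generateWhales(5, p, seed = 3), generateWhales(5, p, seed = 3))
  w <- generateWhales(3, p, seed = 3)
  a <- generateForagingData(w, p, nSequencesPerWhale = 3, seed = 4)
  b <- generateForagingData(w, p, nSequencesPerWhale = 3, seed = 4)
  expect_identical(a$events, b$events)
  expect_identical(a$dives, b$dives)
  expect_identical(a$manifest$sequences, b$manifest$sequences)
  c <- generateForagingData(w, p, nSequencesPerWhale = 3, seed = 5)
  expect_false(identical(a$events, c$events))
})

test_that("zero measurement error reproduces true morphometrics exactly", {
  p <- truthParameters(tlMeasSd = 0, baiMeasSd = 0)
  w <- generateWhales(20, p, seed = 8)
  expect_equal(w$tl_mean, w$tl_true)
  expect_equal(w$bai_mean, w$bai_true)
})

test_that("measurement errors have the generating sd", {
  p <- truthParameters(tlPop = c(mean = 10.5, sd = 1.0), tlMeasSd = 0.3)
  w <- generateWhales(200, p, seed = 9)
  expect_equal(sd(w$tl_mean - w$tl_true), 0.3, tolerance = 0.15)
  expect_true(all(w$tl_true > 0))
  expect_equal(unique(w$tl_sd), 0.3)
})

test_that("invalid generator inputs are rejected", {
  expect_error(generateWhales(0, truthParameters()),
               class = "whalebreath_validation_error")
  expect_error(truthParameters(tacticProbs = c(headstand = 0.5, other = 0.4)),
               class = "whalebreath_validation_error")
  expect_error(truthParameters(tlPop = c(mean = 10, sd = 0)),
               class = "whalebreath_validation_error")
  w <- generateWhales(2, truthParameters(), seed = 1)
  w$whale[1] <- NA
  expect_error(generateForagingData(w, truthParameters()),
               class = "whalebreath_validation_error")
})

test_that("breath counts follow the zero-truncated Poisson law", {
  # all covariate effects zero, intercept log(2), no random intercepts:
  # E[N] = 2 / (1 - exp(-2)) ~ 2.313, checked at n = 10,000 sequences
  p <- flatParams(interceptCount = log(2))
  w <- generateWhales(10, p, seed = 51)
  sim <- generateForagingData(w, p, nSequencesPerWhale = 1000, seed = 52)
  n <- sim$manifest$sequences$n_breaths
  expect_true(all(n >= 1))
  se <- sqrt(ztpoisVar(2) / length(n))
  expect_equal(mean(n), ztpoisMean(2), tolerance = 3 * se / ztpoisMean(2))
})

test_that("degenerate variances make sequence totals exactly log-linear", {
  p <- truthParameters(totalMode = "sequence",
                       ranSd = c(count = 0, total_inhalation = 0, ibi = 0),
                       residSd = c(total_inhalation = 0, ibi = 0),
                       withinSd = c(inhalation = 0, ibi = 0))
  w <- generateWhales(4, p, seed = 61)
  sim <- generateForagingData(w, p, nSequencesPerWhale = 5, seed = 62)
  sq <- sim$manifest$sequences
  expect_equal(sq$total_inhalation_s, exp(sq$lp_total), tolerance = 1e-12)
  expect_equal(sq$mean_ibi_s[sq$n_breaths >= 2],
               exp(sq$lp_ibi[sq$n_breaths >= 2]), tolerance = 1e-12)
})

test_that("recomputed metrics reproduce the manifest in both generation modes", {
  for (mode in c("breath", "sequence")) {
    p <- truthParameters(totalMode = mode)
    w <- generateWhales(4, p, seed = 71)
    sim <- generateForagingData(w, p, nSequencesPerWhale = 6, seed = 72)
    m <- sequenceMetrics(sim$events)
    mm <- merge(m, sim$manifest$sequences, by = c("whale", "sequence"))
    expect_equal(nrow(mm), nrow(sim$manifest$sequences))
    expect_equal(mm$n_breaths.x, mm$n_breaths.y)
    expect_equal(mm$total_inhalation_s.x, mm$total_inhalation_s.y,
                 tolerance = 1e-9)
    idx <- mm$n_breaths.x >= 2
    expect_equal(mm$mean_ibi_s.x[idx], mm$mean_ibi_s.y[idx], tolerance = 1e-9)
  }
})

test_that("breath count and total inhalation duration are strongly correlated", {
  p <- truthParameters()   # default breath-level generation
  w <- generateWhales(30, p, seed = 81)
  sim <- generateForagingData(w, p, nSequencesPerWhale = 20, seed = 82)
  m <- sequenceMetrics(sim$events)
  expect_gt(cor(m$n_breaths, m$total_inhalation_s), 0.9)
})

test_that("depth series stay at the surface when there are no breaths", {
  dv <- data.frame(whale = "W1", dive_id = c("D1", "D2"),
                   start_s = c(0, 200), end_s = c(100, 300),
                   duration_s = 100, behavior = "forage",
                   tactic = "headstand", bubble = 0, max_depth_m = 8)
  ev <- data.frame(whale = character(0), sequence = character(0),
                   breath = integer(0), start_s = numeric(0),
                   end_s = numeric(0))
  ds <- generateDepthSeries(ev, dv)
  t <- sampleTimes(ds)
  between <- t > 100 & t < 200
  expect_true(all(depths(ds)[between] < 0.2))
})

test_that("overlapping dives are rejected", {
  dv <- data.frame(whale = "W1", dive_id = c("D1", "D2"),
                   start_s = c(0, 50), end_s = c(100, 150),
                   duration_s = 100, behavior = "forage",
                   tactic = "headstand", bubble = 0, max_depth_m = 8)
  ev <- data.frame(whale = character(0), sequence = character(0),
                   breath = integer(0), start_s = numeric(0),
                   end_s = numeric(0))
  expect_error(generateDepthSeries(ev, dv),
               class = "whalebreath_validation_error")
})

test_that("travel observations follow the generating log-linear model", {
  p <- truthParameters(travelResidSd = 0, travelRanSd = 0)
  w <- generateWhales(10, p, seed = 91)
  tr <- generateTravelData(w, p, nObsPerWhale = 2, seed = 92)
  expect_equal(log(tr$respiration_rate_bpm), tr$lp, tolerance = 1e-12)
  expect_equal(nrow(tr), 20)
})
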