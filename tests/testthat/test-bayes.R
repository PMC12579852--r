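test_that("z-scoring computes and reuses constants", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1))
  expect_equal(unname(z$constants), c(2, 1))
  # applying stored constants to the mean gives 0; reuse is idempotent
  expect_equal(zscore(2, z$constants)$values, 0)
  expect_identical(zscore(c(5, 9), z$constants)$constants, z$constants)
  expect_error(zscore(c(2, 2, 2)), class = "whalebreath_validation_error")
})

test_that("datasets are assembled per design timing and filters", {
  p <- truthParameters()
  w <- generateWhales(6, p, seed = 101)
  sim <- generateForagingData(w, p, nSequencesPerWhale = 8, seed = 102)
  m <- sequenceMetrics(sim$events)

  dsCount <- buildDataset(modelDesign("recovery_breath_count"), m, sim$dives, w)
  dsIbi <- buildDataset(modelDesign("recovery_ibi"), m, sim$dives, w)
  # single-breath sequences stay in the count model, leave the IBI model
  singles <- m$sequence[m$n_breaths == 1]
  if (length(singles)) {
    expect_true(any(dsCount$sequence %in% singles))
    expect_false(any(dsIbi$sequence %in% singles))
  }
  expect_true(all(dsIbi$response > 0))

  # recovery vs anticipation: same sequences differ only in dive covariates
  dsR <- buildDataset(modelDesign("recovery_total_inhalation"), m, sim$dives, w)
  dsA <- buildDataset(modelDesign("anticipation_total_inhalation"), m,
                      sim$dives, w)
  common <- intersect(dsR$sequence, dsA$sequence)
  expect_gt(length(common), 0)
  r <- dsR[match(common, dsR$sequence), ]
  a <- dsA[match(common, dsA$sequence), ]
  expect_equal(r$response, a$response)
  expect_equal(r$pre_duration_s, a$pre_duration_s)
  # the dive covariates used differ (preceding vs following dive)
  expect_equal(a$tactic, factor(a$post_tactic, levels = levels(a$tactic)))
  expect_equal(r$tactic, factor(r$pre_tactic, levels = levels(r$tactic)))

  # combined design keeps only tactic-matched sequences
  dsC <- buildDataset(modelDesign("combined_total_inhalation"), m, sim$dives, w)
  expect_true(all(dsC$pre_tactic == dsC$post_tactic))
  expect_true(all(c("z_dive_pre", "z_dive_post") %in% names(dsC)))

  expect_error(modelDesign("no_such_design"),
               class = "whalebreath_validation_error")
})

test_that("coefficient summaries report mean, CrI and majority-side percent", {
  s <- coefficientSummary(cbind(b = c(-1, 1, 2, 3)))
  expect_equal(s$mean, 1.25)
  expect_equal(s$pct_over_zero, 75)

  set.seed(5)
  sym <- coefficientSummary(cbind(b = rnorm(20000)))
  expect_equal(sym$pct_over_zero, 50, tolerance = 0.05)
  expect_true(sym$lower95 <= sym$mean && sym$mean <= sym$upper95)

  pos <- coefficientSummary(cbind(b = runif(1000) + 0.1))
  expect_equal(pos$pct_over_zero, 100)
})

test_that("a flat-truth Poisson fit recovers the intercept of the count law", {
  # all effects zero, tiny measurement error: posterior intercept should sit
  # near the lambda solving ztpMean(lambda) = sample mean (asymptotic oracle)
  p <- flatParams(interceptCount = log(2.3))
  p$tlMeasSd <- 0.01
  p$baiMeasSd <- 0.01
  w <- generateWhales(10, p, seed = 111)
  sim <- generateForagingData(w, p, nSequencesPerWhale = 6, seed = 112)
  m <- sequenceMetrics(sim$events)
  des <- modelDesign("recovery_breath_count")
  ds <- buildDataset(des, m, sim$dives, w)
  fit <- fitRespirationModel(des, ds, chains = 2, iterations = 1200,
                             warmup = 400, seed = 113, onFail = "none")
  cs <- coefficientSummary(fit)
  ib <- cs[cs$parameter == "intercept", ]
  mbar <- mean(ds$response)
  lamHat <- uniroot(function(l) l / (1 - exp(-l)) - mbar, c(1e-3, 50))$root
  postSd <- (ib$upper95 - ib$lower95) / (2 * 1.96)
  expect_lt(abs(ib$mean - log(lamHat)), 2 * postSd)
})

test_that("zero measurement sd collapses the latent TL onto the observation", {
  p <- truthParameters(totalMode = "sequence", tlMeasSd = 0, baiMeasSd = 0.01)
  w <- generateWhales(6, p, seed = 121)
  sim <- generateForagingData(w, p, nSequencesPerWhale = 5, seed = 122)
  m <- sequenceMetrics(sim$events)
  des <- modelDesign("recovery_total_inhalation")
  ds <- buildDataset(des, m, sim$dives, w)
  fit <- fitRespirationModel(des, ds, chains = 1, iterations = 800,
                             warmup = 300, seed = 123, onFail = "none",
                             monitorLatent = TRUE)
  dr <- posteriorDraws(fit)
  latent <- dr[, grepl("^tlTrue\\[", colnames(dr)), drop = FALSE]
  expect_equal(ncol(latent), 6)
  obs <- sort(unique(ds$tl_mean))
  expect_equal(unname(sort(colMeans(latent))), obs, tolerance = 1e-3)
  expect_true(all(apply(latent, 2, sd) < 1e-3))
})

test_that("TL measurement uncertainty propagates into the latent posteriors", {
  base <- truthParameters(totalMode = "sequence")
  latentSpread <- function(measSd) {
    p <- base
    p$tlMeasSd <- measSd
    w <- generateWhales(12, p, seed = 131)
    sim <- generateForagingData(w, p, nSequencesPerWhale = 6, seed = 132)
    m <- sequenceMetrics(sim$events)
    des <- modelDesign("recovery_total_inhalation")
    ds <- buildDataset(des, m, sim$dives, w, constants = truthConstants(p))
    fit <- fitRespirationModel(des, ds, chains = 1, iterations = 1000,
                               warmup = 300, seed = 133, onFail = "none",
                               monitorLatent = TRUE)
    dr <- posteriorDraws(fit)
    mean(apply(dr[, grepl("^tlTrue\\[", colnames(dr)), drop = FALSE], 2, sd))
  }
  s1 <- latentSpread(0.05)
  s2 <- latentSpread(0.5)
  # latent true-TL posteriors track the measurement sd when little else
  # constrains them, so uncertainty flows into everything downstream
  expect_gt(s2, 4 * s1)
  expect_equal(s1, 0.05, tolerance = 0.5)
})

test_that("dispersion is near 1 for equidispersed counts and above 1 with heterogeneity", {
  p <- flatParams(interceptCount = log(3))
  p$tlMeasSd <- 0.01
  p$baiMeasSd <- 0.01
  w <- generateWhales(10, p, seed = 141)
  sim <- generateForagingData(w, p, nSequencesPerWhale = 8, seed = 142)
  m <- sequenceMetrics(sim$events)
  des <- modelDesign("recovery_breath_count")
  ds <- buildDataset(des, m, sim$dives, w)
  fit <- fitRespirationModel(des, ds, chains = 1, iterations = 1200,
                             warmup = 400, seed = 143, onFail = "none")
  expect_equal(dispersionStat(fit), 1, tolerance = 0.3)

  # lognormal heterogeneity on the rate inflates the Pearson ratio
  set.seed(144)
  over <- ds
  lamHet <- 3 * exp(rnorm(nrow(ds), -0.32, 0.8))
  over$response <- qpois(runif(nrow(ds), dpois(0, lamHet), 1), lamHet)
  attr(over, "constants") <- attr(ds, "constants")
  fitO <- fitRespirationModel(des, over, chains = 1, iterations = 1200,
                              warmup = 400, seed = 145, onFail = "none")
  expect_gt(dispersionStat(fitO), 1.2)

  expect_error(dispersionStat(smallGaussianFit()),
               class = "whalebreath_validation_error")
})

test_that("residual autocorrelation flags AR(1) structure and not white noise", {
  set.seed(151)
  iid <- rnorm(200)
  a <- residualAcf(iid, lagMax = 5)
  expect_lt(abs(a$acf[1]), a$band[1])

  ar <- as.numeric(arima.sim(list(ar = 0.7), 200))
  b <- residualAcf(ar, lagMax = 5)
  expect_gt(b$acf[1], b$band[1])

  const <- residualAcf(rep(1, 50), lagMax = 5)
  expect_true(attr(const, "degenerate"))
  expect_true(all(is.na(const$acf)))

  expect_error(residualAcf(rnorm(4), lagMax = 10),
               class = "whalebreath_validation_error")
})

test_that("Bayes R2 is bounded and the fitted model explains synthetic signal", {
  fit <- smallGaussianFit()
  r2 <- bayesR2(fit)
  expect_true(r2$lower95 >= 0 && r2$upper95 <= 1)
  expect_true(r2$lower95 <= r2$mean && r2$mean <= r2$upper95)
  # the generating signal (dive duration effect 0.16 over ~1 sd + residual
  # 0.2) puts R2 well away from 0
  expect_gt(r2$mean, 0.1)
})

test_that("plug-in predictions exponentiate the fitted-scale intercepts", {
  cst <- defaultPluginConstants()
  cf <- recoveryCoefficients()
  v <- function(col) setNames(cf[[col]], cf$term)
  atMeans <- list(TL = 10.5, BAI = 27, dive_duration = 120,
                  tactic = "headstand", bubble = 0)
  expect_equal(predictResponse(v("breath_count"), atMeans, cst,
                               family = "poisson")$mean,
               exp(0.83), tolerance = 1e-12)
  ibi <- predictResponse(v("ibi"), atMeans, cst, family = "gaussian_log")
  expect_equal(exp(ibi$meanlog), exp(2.64), tolerance = 1e-12)
  expect_equal(ibi$sdlog, 0)
  tin <- predictResponse(v("total_inhalation"), atMeans, cst,
                         family = "gaussian_log")
  expect_equal(exp(tin$meanlog), exp(1.01), tolerance = 1e-12)
  # forward swimming shifts the count linear predictor by its offset
  fwd <- modifyList(atMeans, list(tactic = "forward_swimming"))
  expect_equal(predictResponse(v("breath_count"), fwd, cst,
                               family = "poisson")$mean,
               exp(0.83 - 0.15), tolerance = 1e-12)
})

test_that("predicting at the training means reproduces the fitted intercept", {
  fit <- smallGaussianFit()
  cst <- standardization(fit)
  atMeans <- list(TL = cst$tl[["mean"]], BAI = cst$bai[["mean"]],
                  dive_duration = cst$dive_duration[["mean"]],
                  tactic = "headstand", bubble = 0)
  pred <- predictResponse(fit, atMeans)
  cs <- coefficientSummary(fit)
  expect_equal(pred$meanlog, cs$mean[cs$parameter == "intercept"],
               tolerance = 1e-9)
})
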