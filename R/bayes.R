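## Bayesian mixed models of respiration with covariate measurement error.
## Model structure: log-linear fixed effects in z-scored TL, BAI and dive
## duration (plus bubble-blast and tactic contrasts), an individual random
## intercept, and latent true TL/BAI imputed from their photogrammetric
## measurement posteriors. Sampled with JAGS.

#' z-score standardization with reusable constants
#'
#' Standardizes values as `(x - mean) / sd`. When `constants` is `NULL` they
#' are computed from the data (sample sd, n - 1 denominator) and returned so
#' the identical transform can be applied at prediction time.
#'
#' @param values numeric vector.
#' @param constants optional `c(mean, sd)` to apply instead of computing.
#' @return list with `values` (standardized) and `constants`.
#' @examples
#' zscore(c(1, 2, 3))$values   # -1 0 1
#' @export
zscore <- function(values, constants = NULL) {
  if (is.null(constants)) {
    wbAssert(length(unique(values[is.finite(values)])) >= 2,
             "need >= 2 distinct values to compute z-score constants")
    constants <- c(mean = mean(values, na.rm = TRUE),
                   sd = sd(values, na.rm = TRUE))
  }
  wbAssert(constants[["sd"]] > 0, "z-score sd must be > 0")
  list(values = (values - constants[["mean"]]) / constants[["sd"]],
       constants = constants)
}

designTable <- function() {
  rbind(
    data.frame(name = "recovery_breath_count", response = "n_breaths",
               family = "poisson", timing = "recovery"),
    data.frame(name = "recovery_total_inhalation", response = "total_inhalation_s",
               family = "gaussian_log", timing = "recovery"),
    data.frame(name = "recovery_ibi", response = "mean_ibi_s",
               family = "gaussian_log", timing = "recovery"),
    data.frame(name = "recovery_accumulation", response = "accumulation_rate",
               family = "gaussian_log", timing = "recovery"),
    data.frame(name = "recovery_initial_duration", response = "initial_inhalation_s",
               family = "gaussian_log", timing = "recovery"),
    data.frame(name = "anticipation_total_inhalation", response = "total_inhalation_s",
               family = "gaussian_log", timing = "anticipation"),
    data.frame(name = "anticipation_ibi", response = "mean_ibi_s",
               family = "gaussian_log", timing = "anticipation"),
    data.frame(name = "anticipation_accumulation", response = "accumulation_rate",
               family = "gaussian_log", timing = "anticipation"),
    data.frame(name = "anticipation_terminal_duration", response = "terminal_inhalation_s",
               family = "gaussian_log", timing = "anticipation"),
    data.frame(name = "combined_total_inhalation", response = "total_inhalation_s",
               family = "gaussian_log", timing = "combined"),
    data.frame(name = "combined_ibi", response = "mean_ibi_s",
               family = "gaussian_log", timing = "combined"),
    data.frame(name = "combined_accumulation", response = "accumulation_rate",
               family = "gaussian_log", timing = "combined"),
    data.frame(name = "travel_respiration_rate", response = "respiration_rate_bpm",
               family = "gaussian_log", timing = "travel"))
}

#' Look up a model design by name
#'
#' The design family: `recovery_*` models attach behavioural covariates
#' (dive duration, bubble blast, foraging tactic) from the dive preceding
#' the surface sequence, `anticipation_*` from the dive following it,
#' `combined_*` use tactic-matched sequences with both dive durations, and
#' `travel_respiration_rate` regresses travel respiration rate on TL, BAI
#' and swim speed. Breath count is Poisson with log link; continuous metrics
#' are Gaussian on the natural-log response.
#'
#' @param name design name; see `designTable` in the source or call with an
#'   unknown name for the list.
#' @return a [ModelDesign-class].
#' @examples
#' modelDesign("recovery_breath_count")
#' @export
modelDesign <- function(name) {
  dt <- designTable()
  if (!name %in% dt$name)
    wbStop(paste0("unknown design '", name, "'; available: ",
                  paste(dt$name, collapse = ", ")))
  row <- dt[dt$name == name, ]
  fe <- switch(row$timing,
    recovery = ,
    anticipation = c("tl", "bai", "dive_duration", "bubble", "tactic"),
    combined = c("tl", "bai", "dive_pre", "dive_post", "tactic"),
    travel = c("tl", "bai", "speed"))
  new("ModelDesign", name = row$name, response = row$response,
      family = row$family, timing = row$timing, fixedEffects = fe,
      randomEffect = "whale")
}

## attach preceding/following dive covariates to sequence metrics by time
attachDives <- function(metrics, dives) {
  dives <- validateTable(dives, "dives")
  pre <- post <- vector("list", nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    dv <- dives[dives$whale == metrics$whale[i], , drop = FALSE]
    p <- dv[dv$end_s <= metrics$first_breath_s[i] + 1e-9, , drop = FALSE]
    f <- dv[dv$start_s >= metrics$last_breath_s[i] - 1e-9, , drop = FALSE]
    pre[[i]] <- if (nrow(p)) p[which.max(p$end_s), ] else NULL
    post[[i]] <- if (nrow(f)) f[which.min(f$start_s), ] else NULL
  }
  get <- function(lst, col, default = NA) {
    vapply(lst, function(d) if (is.null(d) || is.null(d[[col]])) default
           else d[[col]],
           if (is.character(default)) character(1) else numeric(1))
  }
  metrics$pre_duration_s <- get(pre, "duration_s", NA_real_)
  metrics$pre_tactic <- get(pre, "tactic", NA_character_)
  metrics$pre_bubble <- get(pre, "bubble", NA_real_)
  metrics$post_duration_s <- get(post, "duration_s", NA_real_)
  metrics$post_tactic <- get(post, "tactic", NA_character_)
  metrics$post_bubble <- get(post, "bubble", NA_real_)
  metrics
}

#' Assemble a model-ready dataset for a design
#'
#' Joins sequence metrics with the dive covariates selected by the design's
#' timing and with the per-whale morphometric measurement posteriors, drops
#' rows with undefined responses or missing required covariates (e.g. the
#' mean IBI of a single-breath sequence), log-transforms continuous
#' responses, and z-scores the continuous covariates (storing the constants
#' for prediction). Tactic is a factor with headstand as the reference
#' level.
#'
#' @param design a [ModelDesign-class].
#' @param metrics sequence-metrics table from [sequenceMetrics()] (for the
#'   travel design: a travel table with `whale`, `swim_speed_mps`,
#'   `respiration_rate_bpm`).
#' @param dives dive table (ignored for the travel design).
#' @param morph per-whale table with `whale`, `tl_mean`, `tl_sd`,
#'   `bai_mean`, `bai_sd`.
#' @param constants optional named list of `c(mean, sd)` standardization
#'   constants (`tl`, `bai`, `dive_duration`, ...) to apply instead of
#'   computing them from the data.
#' @return data.frame with attributes `constants` and `design`.
#' @examples
#' w <- generateWhales(4, seed = 1)
#' sim <- generateForagingData(w, nSequencesPerWhale = 5, seed = 2)
#' m <- sequenceMetrics(sim$events)
#' ds <- buildDataset(modelDesign("recovery_breath_count"), m, sim$dives, w)
#' nrow(ds)
#' @export
buildDataset <- function(design, metrics, dives = NULL, morph, constants = NULL) {
  stopifnot(is(design, "ModelDesign"))
  morph <- validateTable(morph, "morph")
  wbAssert(!anyDuplicated(morph$whale), "morph table has duplicated whales")
  cst <- list()
  useC <- function(name, values) {
    given <- if (!is.null(constants)) constants[[name]] else NULL
    z <- zscore(values, given)
    cst[[name]] <<- z$constants
    z$values
  }

  if (design@timing == "travel") {
    tr <- validateTable(metrics, "travel")
    ds <- merge(tr, morph[, c("whale", "tl_mean", "tl_sd", "bai_mean", "bai_sd")],
                by = "whale")
    ds <- ds[ds$respiration_rate_bpm > 0, , drop = FALSE]
    ds$y_log <- log(ds$respiration_rate_bpm)
    ds$z_speed <- useC("speed", ds$swim_speed_mps)
  } else {
    wbAssert(!is.null(dives), "dives table required for foraging designs")
    m <- attachDives(metrics, dives)
    resp <- m[[design@response]]
    wbAssert(!is.null(resp), paste("metrics table lacks", design@response))
    keep <- !is.na(resp)
    side <- switch(design@timing, recovery = "pre", anticipation = "post",
                   combined = "both")
    if (side == "pre") {
      keep <- keep & !is.na(m$pre_duration_s) & !is.na(m$pre_tactic)
    } else if (side == "post") {
      keep <- keep & !is.na(m$post_duration_s) & !is.na(m$post_tactic)
    } else {
      keep <- keep & !is.na(m$pre_duration_s) & !is.na(m$post_duration_s) &
        !is.na(m$pre_tactic) & !is.na(m$post_tactic) &
        m$pre_tactic == m$post_tactic
    }
    if (design@family == "gaussian_log") keep <- keep & resp > 0
    ds <- m[keep, , drop = FALSE]
    ds$response <- m[[design@response]][keep]
    if (design@family == "gaussian_log") ds$y_log <- log(ds$response)
    if (side == "pre") {
      ds$z_dive <- useC("dive_duration", ds$pre_duration_s)
      ds$tactic <- ds$pre_tactic
      ds$bubble <- ds$pre_bubble
    } else if (side == "post") {
      ds$z_dive <- useC("dive_duration", ds$post_duration_s)
      ds$tactic <- ds$post_tactic
      ds$bubble <- ds$post_bubble
    } else {
      ds$z_dive_pre <- useC("dive_pre", ds$pre_duration_s)
      ds$z_dive_post <- useC("dive_post", ds$post_duration_s)
      ds$tactic <- ds$pre_tactic
    }
    ds <- merge(ds, morph[, c("whale", "tl_mean", "tl_sd", "bai_mean", "bai_sd")],
                by = "whale")
    if ("tactic" %in% names(ds)) {
      lev <- c("headstand",
               setdiff(sort(unique(ds$tactic)), "headstand"))
      ds$tactic <- factor(ds$tactic, levels = lev)
    }
  }
  wbAssert(nrow(ds) > 0, "dataset is empty after filtering")
  cst$tl <- zscore(ds$tl_mean[!duplicated(ds$whale)],
                   if (!is.null(constants)) constants$tl else NULL)$constants
  cst$bai <- zscore(ds$bai_mean[!duplicated(ds$whale)],
                    if (!is.null(constants)) constants$bai else NULL)$constants
  rownames(ds) <- NULL
  attr(ds, "constants") <- cst
  attr(ds, "design") <- design@name
  ds
}

## fixed-effect design matrix (everything except TL/BAI, which are latent)
fixedDesignMatrix <- function(design, ds) {
  cols <- list(intercept = rep(1, nrow(ds)))
  if (design@timing %in% c("recovery", "anticipation")) {
    cols$dive_duration <- ds$z_dive
    cols$bubble <- as.numeric(ds$bubble)
  } else if (design@timing == "combined") {
    cols$dive_pre <- ds$z_dive_pre
    cols$dive_post <- ds$z_dive_post
  } else {
    cols$speed <- ds$z_speed
  }
  if (!is.null(ds$tactic)) {
    for (lev in levels(ds$tactic)[-1]) {
      if (any(ds$tactic == lev))
        cols[[paste0("tactic_", lev)]] <- as.numeric(ds$tactic == lev)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)[vapply(cols, length, 1L) > 0]
  X
}

jagsModelString <- function(family, truncated) {
  lik <- if (family == "poisson" && truncated) "
    y[i] ~ dpois(exp(mu[i])) T(1,)" else if (family == "poisson") "
    y[i] ~ dpois(exp(mu[i]))" else "
    y[i] ~ dnorm(mu[i], tauRes)"
  sigma <- if (family == "gaussian_log") "
  sigma ~ dexp(sdRate)
  tauRes <- 1 / (sigma * sigma)" else ""
  paste0("model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], beta[]) + bTL * ztl[w[i]] + bBAI * zbai[w[i]] + u[w[i]]", lik, "
  }
  for (j in 1:W) {
    tlTrue[j] ~ dnorm(tlObs[j], tlPrec[j])
    baiTrue[j] ~ dnorm(baiObs[j], baiPrec[j])
    ztl[j] <- (tlTrue[j] - tlC[1]) / tlC[2]
    zbai[j] <- (baiTrue[j] - baiC[1]) / baiC[2]
    uz[j] ~ dnorm(0, 1)
    u[j] <- sigmaU * uz[j]
  }
  for (k in 1:P) { beta[k] ~ dnorm(b0[k], betaPrec[k]) }
  bTL ~ dnorm(0, 1)
  bBAI ~ dnorm(0, 1)
  sigmaU ~ dexp(sdRate)", sigma, "
}")
}

#' Fit a Bayesian respiration mixed model
#'
#' Fits the design's log-linear mixed model with JAGS. True TL and BAI enter
#' as latent variables with independent normal priors given by each whale's
#' reported measurement mean and sd, and are z-scored inside the model with
#' the dataset's standardization constants, so photogrammetric uncertainty
#' propagates into the coefficient posteriors. The individual random
#' intercept uses a non-centred parameterization. Breath-count models can
#' use the zero-truncated Poisson likelihood (every surfacing contains at
#' least one breath); this is the default for the Poisson family.
#'
#' Priors (configurable): Normal(0, 1) for standardized-covariate and tactic
#' coefficients; Normal(m, 2) for the intercept with `m` the empirical
#' response-scale centre; Exponential(1) for the random-intercept and
#' residual sds.
#'
#' Convergence contract: R-hat < 1.01 and effective sample size > 400 for
#' every reported parameter; violations raise a
#' `whalebreath_diagnostics_failure` (or a warning, per `onFail`).
#'
#' @param design a [ModelDesign-class].
#' @param dataset model-ready data from [buildDataset()].
#' @param priors list overriding `betaSd`, `interceptSd`, `interceptMean`,
#'   `sdRate`.
#' @param chains,iterations,warmup MCMC settings. `iterations` counts
#'   post-adaptation iterations per chain including `warmup` burn-in.
#'   Reference settings for full analyses are 3 chains of 90,000 with 30,000
#'   warm-up (travel: 30,000 with 10,000); defaults here are test scale.
#' @param seed integer RNG seed.
#' @param truncated logical; zero-truncated Poisson likelihood (default TRUE
#'   for the Poisson family, ignored otherwise).
#' @param onFail `"error"`, `"warn"` or `"none"` when the convergence
#'   contract fails.
#' @param monitorLatent also monitor the latent true TL values (columns
#'   `tlTrue[...]` in the draws), e.g. to inspect the measurement-error
#'   imputation.
#' @return a [RespirationFit-class].
#' @examples
#' \donttest{
#' w <- generateWhales(8, seed = 1)
#' sim <- generateForagingData(w, nSequencesPerWhale = 6, seed = 2)
#' m <- sequenceMetrics(sim$events)
#' des <- modelDesign("recovery_breath_count")
#' ds <- buildDataset(des, m, sim$dives, w)
#' fit <- fitRespirationModel(des, ds, chains = 2, iterations = 1500,
#'                            warmup = 500, seed = 3, onFail = "warn")
#' coefficientSummary(fit)
#' }
#' @export
fitRespirationModel <- function(design, dataset, priors = list(),
                                chains = 3, iterations = 3000, warmup = 1000,
                                seed = 1, truncated = NULL,
                                onFail = c("error", "warn", "none"),
                                monitorLatent = FALSE) {
  stopifnot(is(design, "ModelDesign"))
  onFail <- match.arg(onFail)
  wbAssert(nrow(dataset) > 0, "empty dataset")
  wbAssert(iterations > warmup, "iterations must exceed warmup")
  cst <- attr(dataset, "constants")
  wbAssert(!is.null(cst), "dataset lacks standardization constants; use buildDataset()")
  if (is.null(truncated)) truncated <- design@family == "poisson"
  truncated <- truncated && design@family == "poisson"

  pr <- list(betaSd = 1, interceptSd = 2, interceptMean = NULL, sdRate = 1)
  pr[names(priors)] <- priors

  X <- fixedDesignMatrix(design, dataset)
  whales <- sort(unique(dataset$whale))
  w <- match(dataset$whale, whales)
  wm <- dataset[!duplicated(dataset$whale), , drop = FALSE]
  wm <- wm[match(whales, wm$whale), , drop = FALSE]

  y <- if (design@family == "poisson") as.numeric(dataset$response)
       else dataset$y_log
  if (design@family == "poisson")
    wbAssert(all(y == round(y)) && all(y >= (if (truncated) 1 else 0)),
             "Poisson response must be counts (>= 1 when truncated)")
  interceptMean <- if (!is.null(pr$interceptMean)) pr$interceptMean
    else if (design@family == "poisson") log(mean(y)) else mean(y)
  P <- ncol(X)
  b0 <- c(interceptMean, rep(0, P - 1))
  betaPrec <- c(1 / pr$interceptSd^2, rep(1 / pr$betaSd^2, P - 1))

  data <- list(N = nrow(dataset), W = length(whales), X = X, w = w, y = y,
               tlObs = wm$tl_mean, tlPrec = 1 / pmax(wm$tl_sd, 1e-6)^2,
               baiObs = wm$bai_mean, baiPrec = 1 / pmax(wm$bai_sd, 1e-6)^2,
               tlC = unname(cst$tl), baiC = unname(cst$bai),
               b0 = b0, betaPrec = betaPrec, P = P, sdRate = pr$sdRate)

  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000 + k) %% 2147483647)
  })
  model <- rjags::jags.model(
    textConnection(jagsModelString(design@family, truncated)),
    data = data, inits = inits, n.chains = chains, n.adapt = 500,
    quiet = TRUE)
  stats::update(model, warmup, progress.bar = "none")
  monitor <- c("beta", "bTL", "bBAI", "sigmaU", "mu",
               if (design@family == "gaussian_log") "sigma",
               if (monitorLatent) "tlTrue")
  samp <- rjags::coda.samples(model, monitor, n.iter = iterations - warmup,
                              progress.bar = "none")

  nm <- colnames(samp[[1]])
  betaIdx <- grep("^beta\\[", nm)
  rename <- nm
  rename[betaIdx] <- colnames(X)[as.integer(gsub("beta\\[|\\]", "", nm[betaIdx]))]
  rename[nm == "bTL"] <- "tl"
  rename[nm == "bBAI"] <- "bai"
  rename[nm == "sigmaU"] <- "sd_individual"
  rename[nm == "sigma"] <- "sd_residual"
  for (k in seq_along(samp)) colnames(samp[[k]]) <- rename

  keepCols <- !grepl("^mu\\[", rename)
  diag <- local({
    sub <- lapply(samp, function(m) m[, keepCols, drop = FALSE])
    ess <- tryCatch(coda::effectiveSize(coda::as.mcmc.list(
      lapply(sub, coda::as.mcmc))), error = function(e) rep(NA_real_, sum(keepCols)))
    rhat <- if (chains >= 2) {
      g <- tryCatch(coda::gelman.diag(coda::as.mcmc.list(
        lapply(sub, coda::as.mcmc)), multivariate = FALSE,
        autoburnin = FALSE)$psrf[, 1], error = function(e) rep(NA_real_, sum(keepCols)))
      g
    } else rep(NA_real_, sum(keepCols))
    data.frame(parameter = rename[keepCols], rhat = unname(rhat),
               ess = unname(ess))
  })

  all <- do.call(rbind, samp)
  fit <- new("RespirationFit", design = design,
             draws = all[, keepCols, drop = FALSE],
             mu = all[, !keepCols, drop = FALSE],
             dataset = dataset, constants = cst, diagnostics = diag,
             truncated = truncated,
             mcmc = list(chains = chains, iterations = iterations,
                         warmup = warmup, seed = seed))

  bad <- with(diag, (is.finite(rhat) & rhat >= 1.01) | (is.finite(ess) & ess <= 400))
  bad <- bad & !grepl("^tlTrue\\[", diag$parameter)
  if (any(bad, na.rm = TRUE) && onFail != "none") {
    msg <- paste0("convergence contract failed for: ",
                  paste(diag$parameter[bad], collapse = ", "),
                  " (max R-hat ", round(max(diag$rhat, na.rm = TRUE), 4),
                  ", min ESS ", round(min(diag$ess, na.rm = TRUE)), ")")
    if (onFail == "error")
      stop(errorCondition(msg, class = c("whalebreath_diagnostics_failure",
                                         "error")))
    warning(msg)
  }
  fit
}

#' Summarize posterior coefficients
#'
#' Posterior mean, central 95% credible interval (2.5 and 97.5 percentiles)
#' and the percentage of the posterior on the majority side of zero, per
#' reported parameter, mirroring the usual coefficient-table layout.
#'
#' @param object a [RespirationFit-class] or a matrix of posterior draws
#'   (>= 1,000 rows recommended).
#' @return data.frame: `parameter`, `mean`, `lower95`, `upper95`,
#'   `pct_over_zero`.
#' @examples
#' coefficientSummary(cbind(b = c(-1, 1, 2, 3)))
#' @export
coefficientSummary <- function(object) {
  draws <- if (is(object, "RespirationFit")) object@draws else as.matrix(object)
  out <- lapply(colnames(draws), function(p) {
    d <- draws[, p]
    q <- unname(quantile(d, c(0.025, 0.975)))
    pp <- mean(d > 0)
    data.frame(parameter = p, mean = mean(d), lower95 = q[1], upper95 = q[2],
               pct_over_zero = 100 * max(pp, 1 - pp))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bayes R-squared
#'
#' Per posterior draw, the ratio of fitted-value variance to fitted plus
#' residual variance. For the Gaussian log-response family the residual
#' variance is `sigma^2` on the log scale; for the Poisson family the
#' decomposition uses the response scale with residual variance `mean(lambda)`
#' (the Poisson variance at the fitted means).
#'
#' @param fit a [RespirationFit-class].
#' @return data.frame with `mean`, `lower95`, `upper95` of the per-draw R2.
#' @export
bayesR2 <- function(fit) {
  stopifnot(is(fit, "RespirationFit"))
  mu <- fit@mu
  if (fit@design@family == "gaussian_log") {
    sig <- fit@draws[, "sd_residual"]
    r2 <- apply(mu, 1, var) / (apply(mu, 1, var) + sig^2)
  } else {
    lam <- exp(mu)
    vf <- apply(lam, 1, var)
    r2 <- vf / (vf + rowMeans(lam))
  }
  q <- unname(quantile(r2, c(0.025, 0.975)))
  data.frame(mean = mean(r2), lower95 = q[1], upper95 = q[2])
}

## zero-truncated Poisson mean/variance
ztpMean <- function(lambda) lambda / (1 - exp(-lambda))
ztpVar <- function(lambda) {
  m <- ztpMean(lambda)
  m * (1 + lambda - m)
}

#' Pearson dispersion statistic for Poisson fits
#'
#' Summed squared Pearson residuals at the posterior-mean fitted values,
#' divided by the residual degrees of freedom (n minus the number of
#' fixed-effect coefficients). Values near 1 indicate equidispersion at the
#' fitted means; evaluating at the posterior mean (rather than averaging
#' over draws) keeps the statistic from conflating posterior spread with
#' data overdispersion. Truncated fits use the zero-truncated Poisson mean
#' and variance.
#'
#' @param fit a [RespirationFit-class] with Poisson family.
#' @return dispersion ratio (scalar).
#' @export
dispersionStat <- function(fit) {
  stopifnot(is(fit, "RespirationFit"))
  if (fit@design@family != "poisson")
    wbStop("dispersion statistic is defined for Poisson fits only")
  y <- as.numeric(fit@dataset$response)
  nm <- colnames(fit@draws)
  p <- sum(!nm %in% c("sd_individual", "sd_residual") & !grepl("^tlTrue\\[", nm))
  n <- length(y)
  if (n <= p) wbStop("need more observations than fixed-effect parameters")
  lam <- exp(colMeans(fit@mu))
  if (fit@truncated) {
    e <- ztpMean(lam); v <- ztpVar(lam)
  } else {
    e <- lam; v <- lam
  }
  sum((y - e)^2 / v) / (n - p)
}

#' Residual autocorrelation check
#'
#' Lag-1..K autocorrelations of (posterior-mean) residuals in the supplied
#' ordering, with the approximate 95% white-noise band `+/- 1.96 / sqrt(n)`.
#' Constant residual series have undefined autocorrelation and are flagged.
#'
#' @param x a [RespirationFit-class] or a numeric residual vector, assumed
#'   time-ordered within deployment.
#' @param lagMax largest lag (default 10).
#' @return data.frame `lag`, `acf`, `band` with attribute
#'   `degenerate = TRUE` when the series is constant.
#' @export
residualAcf <- function(x, lagMax = 10) {
  res <- if (is(x, "RespirationFit")) {
    fitm <- colMeans(x@mu)
    if (x@design@family == "gaussian_log") x@dataset$y_log - fitm
    else {
      lam <- exp(fitm)
      e <- if (x@truncated) ztpMean(lam) else lam
      (as.numeric(x@dataset$response) - e) / sqrt(if (x@truncated) ztpVar(lam) else lam)
    }
  } else as.numeric(x)
  n <- length(res)
  if (n < lagMax + 1) wbStop("residual series shorter than lagMax + 1")
  if (sd(res) == 0) {
    out <- data.frame(lag = seq_len(lagMax), acf = NA_real_,
                      band = 1.96 / sqrt(n))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  a <- acf(res, lag.max = lagMax, plot = FALSE)$acf[-1]
  out <- data.frame(lag = seq_len(lagMax), acf = as.numeric(a),
                    band = 1.96 / sqrt(n))
  attr(out, "degenerate") <- FALSE
  out
}

#' Predict response-scale parameters at a covariate combination
#'
#' Evaluates the linear predictor at a covariate combination standardized
#' with the supplied (or stored) constants, with the individual random
#' intercept at zero. Returns the Poisson mean for count responses, or the
#' lognormal `(meanlog, sdlog)` for Gaussian log-response models.
#'
#' @param object a [RespirationFit-class] (posterior-mean coefficients and
#'   stored constants are used), or a named coefficient vector with elements
#'   `intercept`, `tl`, `bai`, `dive_duration`, `bubble` and optional
#'   `tactic_*` offsets (reference tactic: headstand).
#' @param combo list/row with `TL` (m), `BAI`, `dive_duration` (s), `tactic`,
#'   `bubble` (0/1).
#' @param constants named list of `c(mean, sd)` for `tl`, `bai`,
#'   `dive_duration`; required when `object` is a coefficient vector.
#' @param family `"poisson"` or `"gaussian_log"`; required for coefficient
#'   vectors.
#' @param sdlog residual sd on the log scale for `"gaussian_log"` (default 0:
#'   point prediction at the posterior means).
#' @return list with `family` and either `mean` (Poisson) or
#'   `meanlog`/`sdlog`.
#' @examples
#' cf <- c(intercept = 0.83, tl = 0.07, bai = 0.11, dive_duration = 0.16,
#'         bubble = -0.02)
#' cst <- list(tl = c(mean = 10.5, sd = 1.5), bai = c(mean = 27, sd = 5),
#'             dive_duration = c(mean = 120, sd = 120))
#' predictResponse(cf, list(TL = 10.5, BAI = 27, dive_duration = 120,
#'                          tactic = "headstand", bubble = 0),
#'                 cst, family = "poisson")$mean   # exp(0.83)
#' @export
predictResponse <- function(object, combo, constants = NULL, family = NULL,
                            sdlog = 0) {
  if (is(object, "RespirationFit")) {
    cs <- coefficientSummary(object)
    coefs <- setNames(cs$mean, cs$parameter)
    if (is.null(constants)) constants <- object@constants
    family <- object@design@family
    if (family == "gaussian_log" && "sd_residual" %in% names(coefs) &&
        missing(sdlog))
      sdlog <- unname(coefs[["sd_residual"]])
  } else {
    coefs <- object
  }
  wbAssert(!is.null(constants) && all(c("tl", "bai") %in% names(constants)),
           "standardization constants (tl, bai, ...) are required")
  wbAssert(!is.null(family), "family is required for coefficient-vector input")
  ztl <- (combo$TL - constants$tl[["mean"]]) / constants$tl[["sd"]]
  zbai <- (combo$BAI - constants$bai[["mean"]]) / constants$bai[["sd"]]
  lp <- unname(coefs[["intercept"]]) + unname(coefs[["tl"]]) * ztl +
    unname(coefs[["bai"]]) * zbai
  if (!is.null(combo$dive_duration) && "dive_duration" %in% names(coefs)) {
    wbAssert("dive_duration" %in% names(constants),
             "dive_duration constants are required")
    zd <- (combo$dive_duration - constants$dive_duration[["mean"]]) /
      constants$dive_duration[["sd"]]
    lp <- lp + unname(coefs[["dive_duration"]]) * zd
  }
  if (!is.null(combo$bubble) && "bubble" %in% names(coefs))
    lp <- lp + unname(coefs[["bubble"]]) * combo$bubble
  if (!is.null(combo$tactic) && combo$tactic != "headstand") {
    key <- paste0("tactic_", combo$tactic)
    if (key %in% names(coefs)) lp <- lp + unname(coefs[[key]])
  }
  if (family == "poisson") list(family = "poisson", mean = exp(lp))
  else list(family = "gaussian_log", meanlog = lp, sdlog = sdlog)
}

#' Bundled plug-in coefficients for the recovery models
#'
#' Posterior-mean coefficient sets for the recovery-design models of breath
#' count, total inhalation duration and mean inter-breath interval in PCFG
#' gray whales, as used by the daily FMR simulation when no freshly fitted
#' models are supplied. Tactic offsets are contrasts against headstanding.
#'
#' @return data.frame with columns `term`, `breath_count`,
#'   `total_inhalation`, `ibi`.
#' @examples
#' recoveryCoefficients()
#' @export
recoveryCoefficients <- function() {
  path <- system.file("extdata", "recovery_coefficients.csv",
                      package = "whalebreath")
  wbAssert(nzchar(path), "bundled coefficient file not found")
  read.csv(path, stringsAsFactors = FALSE)
}
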