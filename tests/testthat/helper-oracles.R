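# Independent brute-force oracles, deliberately written with different code
# paths (lm() for slopes, explicit loops for sums/gaps) than the package.

bruteSequenceMetrics <- function(start, end) {
  n <- length(start)
  inh <- numeric(n)
  for (i in seq_len(n)) inh[i] <- (end[i] - start[i]) / 2
  gaps <- c()
  if (n >= 2) for (i in 1:(n - 1)) gaps <- c(gaps, start[i + 1] - end[i])
  slope <- NA_real_
  if (n >= 2) {
    x <- start - start[1]
    y <- cumsum(inh)
    slope <- unname(coef(lm(y ~ x))[2])
  }
  list(n_breaths = n,
       sequence_duration_s = start[n] - start[1],
       total_inhalation_s = sum(inh),
       mean_ibi_s = if (n >= 2) sum(gaps) / length(gaps) else NA_real_,
       accumulation_rate = slope,
       initial_inhalation_s = inh[1],
       terminal_inhalation_s = if (n >= 2) inh[n] else NA_real_)
}

# random well-formed breath sequence (times in s)
randomSequence <- function(maxBreaths = 8) {
  n <- sample.int(maxBreaths, 1)
  start <- numeric(n)
  end <- numeric(n)
  t <- runif(1, 0, 1000)
  for (i in seq_len(n)) {
    start[i] <- t
    end[i] <- t + runif(1, 0.2, 4)
    t <- end[i] + runif(1, 0.5, 40)
  }
  list(start = start, end = end)
}

# zero-truncated Poisson moments (closed form)
ztpoisMean <- function(lambda) lambda / (1 - exp(-lambda))
ztpoisVar <- function(lambda) {
  m <- ztpoisMean(lambda)
  m * (1 + lambda - m)
}

# truth parameters with all covariate effects removed and a given intercept
flatParams <- function(interceptCount = log(2), ranSd0 = TRUE, ...) {
  zero <- function(cc, int) {
    cc[] <- 0
    cc[["intercept"]] <- int
    cc
  }
  p <- truthParameters(...)
  p$coefs$count <- zero(p$coefs$count, interceptCount)
  p$coefs$total_inhalation <- zero(p$coefs$total_inhalation, 1.01)
  p$coefs$ibi <- zero(p$coefs$ibi, 2.64)
  if (ranSd0) p$ranSd[] <- 0
  p
}

# one small shared Gaussian fit, computed lazily and cached for the session
.fitCache <- new.env(parent = emptyenv())
smallGaussianFit <- function() {
  if (is.null(.fitCache$gauss)) {
    p <- truthParameters(totalMode = "sequence")
    w <- generateWhales(10, p, seed = 401)
    sim <- generateForagingData(w, p, nSequencesPerWhale = 6, seed = 402)
    m <- sequenceMetrics(sim$events)
    des <- modelDesign("recovery_total_inhalation")
    ds <- buildDataset(des, m, sim$dives, w)
    .fitCache$gauss <- fitRespirationModel(des, ds, chains = 2,
                                           iterations = 1500, warmup = 500,
                                           seed = 403, onFail = "none")
  }
  .fitCache$gauss
}
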