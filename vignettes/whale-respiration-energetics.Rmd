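---
title: "Respiration metrics and daily energetics of shallow-diving gray whales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration metrics and daily energetics of shallow-diving gray whales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalebreath)
```

## The scientific problem

Pacific Coast Feeding Group (PCFG) gray whales forage in very shallow
coastal habitat (< 20 m), where buoyancy works against a diving whale for
the whole dive and oxygen management differs sharply from the deep-diving
pattern typical of baleen whales. Because respirometry is infeasible for
free-ranging whales, surface respiration — when, how often, and for how long
a whale breathes between dives — is the accessible proxy for oxygen
consumption and hence energy expenditure.

`whalebreath` implements that proxy chain end to end:

1. **Surface-sequence metrics** from drone-annotated breath events;
2. **Dive and breath detection** from tag depth records;
3. **Bayesian mixed models** relating respiration to body length (TL), body
   condition (BAI), dive duration and foraging behaviour, while propagating
   photogrammetric measurement uncertainty;
4. A **Monte Carlo simulator of daily field metabolic rate (FMR)** that
   converts model-predicted respiration into daily tidal volume, energy use
   and prey requirements across a covariate grid, compared with Cohen's d.

A synthetic-data generator with fully known parameters stands in for field
data, so every stage is testable against ground truth.

## Respiration metrics

A *surface sequence* runs from the first breath after a dive to the last
breath before the next dive. A recorded breath spans the exhalation plus the
immediately following inhalation; since the two have equal durations in gray
whales, the inhalation duration is half the recorded breath duration.
Per sequence we compute: breath count; total inhalation duration (the sum of
per-breath inhalation durations — a tidal-volume proxy); the mean
inter-breath interval (IBI); the inhalation accumulation rate (the
least-squares slope of cumulative inhalation time against time since the
first breath — a recovery-speed proxy combining breath size and rate); and
the initial/terminal breath durations.

Conventions chosen where the definitions leave room:

* Sequence duration is measured start-of-initial to start-of-terminal breath
  (symmetric endpoints).
* The IBI is the *gap* from one breath's end to the next breath's start.
  This keeps dive time, IBIs and inhalation time disjoint, which the FMR
  simulator relies on when it adds them into a dive–recovery cycle.
* The accumulation slope keeps a free intercept and includes the current
  breath's inhalation in the cumulative sum; it needs at least two breaths.
* Undefined metrics (IBI or slope of a single-breath sequence) are reported
  as `NA`, never 0. A single-breath sequence is classed `initial` only.
* Body-condition (BAI) measurements are matched to an observation date
  same-day first, else nearest within ±14 days, ties to the earlier date.
* Nares area is standardized by TL. Whether the natural divisor is TL or
  TL² is genuinely open; area/TL is the default and the exponent is an
  argument (`power`).

## Tag processing

Dives are maximal runs of depth ≥ 0.2 m; crossings are sample-aligned
(half-open), so a dive's duration is the number of submerged samples times
the sampling period — deterministic and resolution-independent for dives
much longer than the sampling interval. A minimum duration (default 5 s)
suppresses spray/noise, and an optional minimum depth separates whale-scale
dives from the sub-metre submergences that punctuate breaths within a
surface sequence; `detectBreaths()` uses 1 m for that separation.

Within a surface period, every sub-threshold surfacing counts as one breath.
A surfacing longer than 10 s is counted as two breaths — "at least two" as a
minimum-count convention — and flagged, because how much longer than 10 s a
surfacing is carries no further information in this rule. Counts are
therefore minimum estimates. Consecutive travel dives form a travel series,
and the tag travel respiration rate pools minimum counts over pooled series
time.

## Bayesian respiration models

The model family mirrors the design table of the analysis it implements:
*recovery* designs attach dive duration, bubble-blast occurrence and
foraging tactic from the dive preceding the sequence, *anticipation* designs
from the following dive, the *combined* designs keep only tactic-matched
sequences and carry both dive durations, and the *travel* design regresses
travel respiration rate on TL, BAI and swim speed. Breath counts use a
Poisson log link; continuous metrics are Gaussian on the natural-log
response. Every model has an individual random intercept (non-centred).

Measurement error: each whale's TL and BAI enter as latent true values with
independent normal priors given by the reported photogrammetric mean and sd,
z-scored inside the model with the dataset's standardization constants. The
coefficient posteriors therefore widen as measurement uncertainty grows.
Z-scoring uses the sample sd (n − 1); constants are stored with the fit and
are required for prediction.

Priors default to Normal(0, 1) for standardized-covariate and tactic
coefficients, Normal(empirical centre, 2) for the intercept, and
Exponential(1) for sd parameters — weakly informative on the log scales
involved, and configurable. The tactic reference level is headstanding; the
bubble-blast reference is "absent".

Because a surfacing implies at least one breath, synthetic breath counts are
zero-truncated. The Poisson family therefore defaults to the zero-truncated
likelihood (`truncated = TRUE`), which makes simulation-based parameter
recovery well posed; the plain Poisson remains available.

Sampling uses JAGS. Reference settings for full analyses are three chains of
90,000 iterations with 30,000 warm-up (30,000/10,000 for the travel model);
the package defaults are test-scale (3 × 3,000/1,000). The convergence
contract — R-hat < 1.01 and effective sample size > 400 per reported
parameter — is checked on every fit; `onFail` selects whether a violation is
an error or a warning, since short test-scale chains can sit at the
contract's edge without invalidating an interval-coverage check.

Model criticism helpers: `bayesR2()` (per-draw fitted/total variance ratio;
residual variance is σ² on the log scale for Gaussian models and the Poisson
variance at the fitted means on the response scale for count models),
`dispersionStat()` (posterior-mean Pearson ratio, using zero-truncated
moments when the fit is truncated), and `residualAcf()` (lag
autocorrelations of posterior-mean residuals with the ±1.96/√n band;
constant series are flagged as degenerate rather than given an ACF).

## The daily FMR simulator

Daily FMR follows the tidal-volume route:

* V_T(daily) = −7.24 + 2.14 · t_in(daily) · TL², litres, where t_in(daily)
  is the summed inhalation time over the day (s) and TL is in metres;
* FMR = H · %O₂ · V_T(daily), with H = 0.002 MJ per litre O₂ and the O₂
  extraction fraction drawn once per simulated day from Normal(0.11, 0.027)
  truncated to (0, 1);
* prey requirement = FMR / (1.91 kJ g⁻¹), reported in metric tons.

The day is split by the activity budget (36% foraging, 43% searching, 21%
travelling; search and travel pooled). Foraging time fills with
dive–recovery cycles: the dive duration, a breath count drawn zero-truncated
Poisson around the predicted mean, that many IBIs at one lognormal draw per
cycle, and one total-inhalation draw. Travel time alternates lognormal
breath-hold (log mean 3.66, log sd 0.65) and inhalation (0.26, 0.17) draws.
In both cases cycles accumulate until the cumulative time first reaches or
exceeds the budget; the crossing cycle counts in full, so the overshoot is
less than one cycle per day (bias < 0.5%).

Numerical choices worth knowing:

* Predictions at a covariate combination are plug-in posterior means by
  default (`sdlog = 0`), with the random intercept at zero. Sampling with
  residual spread, or predictions from a freshly fitted model, are opt-in.
  Individual-level variance is deliberately excluded from the grid
  comparisons so that Cohen's d isolates the covariate contrasts.
* One O₂ draw per day (not per breath): oxygen extraction efficiency is
  treated as a slowly varying physiological state.
* Each grid combination runs under an independent RNG substream derived
  from the root seed, so combinations stay comparable across configuration
  changes, and Cohen's d is exactly invariant (to floating-point rounding,
  < 1e-12) under rescaling of H or prey energy density.
* The default standardization constants for plug-in prediction are TL
  10.5/1.5 m, BAI 27/5, dive duration 120/120 s — central values for the
  PCFG population and grid; they are configurable and logged with results.
* Direct per-iteration conversion of FMR to prey mass is used throughout
  (191 MJ at 1.91 kJ/g is exactly 0.1 t); published per-combination prey
  figures rounded through a different path can differ by a few percent.
* H = 0.002 MJ/L is used as printed for this system; the conventional
  oxygen caloric equivalent is ≈ 0.0201 MJ/L, and absolute FMR magnitudes
  scale linearly with this constant, while all d-based outputs are
  invariant to it.

The grid defaults to TL {9, 12} m × BAI {22, 27, 32} × dive duration
{60, 120, 300} s × tactic {headstand, forward swimming} (36 combinations;
20,000 days each). Comparison families (TL 12–9; BAI 27–22, 32–22, 32–27;
dive 120–300, 60–120, 60–300; headstand–forward) report the mean and sd of
Cohen's d — pooled sd √((s₁² + s₂²)/2) — and of the FMR and prey differences
across all matched pairs.

```{r grid, eval = FALSE}
res <- runFMRGrid(fmrConfig(iterations = 20000, seed = 1))
effectSizes(res)
```

## The synthetic-data generator

`truthParameters()` pins down the full generating model: log-linear
coefficients for breath count, total inhalation duration and IBI (defaults
mirror recovery-model posterior means for this system, so synthetic data
have realistic scales: 2–3 breaths per surfacing, ~14 s IBIs, dives of a few
minutes, TL ~10.5 ± 1.5 m with 0.3 m measurement sd, BAI ~27 ± 5 with
measurement sd 1); individual random intercepts; lognormal dive durations
(median 120 s, log-sd 0.5, a realistic spread for shallow foraging dives);
tactic frequencies dominated by headstanding and forward swimming; and a 25%
bubble-blast rate. These defaults are the package's study conditions and are
not retuned per analysis.

Two generation modes control total inhalation duration. The default
`"breath"` mode draws per-breath inhalation durations whose expectation
follows the log-linear model; the sequence total is the realized sum, which
reproduces the strong empirical coupling between breath count and total
inhalation duration (Pearson ≈ 0.93 on defaults, matching what field data
show). The `"sequence"` mode draws the total itself lognormally at its
linear predictor — the exact generative counterpart of the fitted Gaussian
log-response model — and is what parameter-recovery checks use; with all sds
at zero it is fully deterministic, which the degenerate-limit tests
exploit. Within-sequence gaps are scaled lognormal weights around the drawn
mean IBI, since only the sequence mean is modelled; the within-sequence
variance is a free parameter, not an asserted value.

Depth series are rendered with surfacing breaths at 0.05 m, between-breath
submergences at 0.5 m, and trapezoidal dive profiles (25% descent, 50%
bottom, 25% ascent) to each dive's maximum depth — profiles are not informed
by real descent kinematics and are only meant to be unambiguous for
threshold-based detection. The default test sampling rate is 1 Hz (10 Hz
available).

What the generator does **not** emulate: photogrammetric imagery, GPS drift,
behaviour misclassification, within-day activity rhythms, or dependence
between consecutive sequences beyond the shared individual intercept.
Passing tests therefore validate the *computational* chain — definitions,
detection, inference, simulation — on data whose structure matches the
modelling assumptions; they cannot certify the models against the messier
structure of real field data.

## Verification strategy and problem sizes

The test suite checks, among others: every sequence metric against an
independent brute-force implementation on 1,000 random sequences (at
1e-9); exact breath-count recovery from noiseless 1 Hz depth series;
zero-truncated Poisson count calibration at 10,000 sequences; 95%
credible-interval coverage of the generating coefficients for the recovery
breath-count and total-inhalation models over 20 replicates of 50 whales ×
10 sequences at test-scale MCMC (coverage ≥ 90% pooled over coefficients);
the degenerate-variance FMR chain against hand-computed closed forms (343
foraging cycles from a 31,104 s budget at a 90.75 s cycle); travel sampling
against lognormal moments at ~10,000 cycles; H-invariance of Cohen's d at
1e-12; and the grid effect sizes at 5,000 days per combination. These sizes
were chosen to make Monte Carlo error small relative to each check's
tolerance while keeping the default suite quick to run.

## Known limitations

* The bundled plug-in coefficients are posterior means; grid contrasts for
  covariates whose effects interact with posterior spread (notably the BAI
  and dive-duration families) are smaller under plug-in prediction than
  under full posterior sampling. The TL and tactic contrasts are robust to
  this choice.
* A simulated day uses a single dive duration; mixing realistic dive
  duration distributions within a day is out of scope.
* The tag breath-count route gives minimum counts; surfacings much longer
  than 10 s still count as two breaths (flagged), so tag respiration rates
  are conservative.
* No offset for surface-sequence duration is used in the count models.
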