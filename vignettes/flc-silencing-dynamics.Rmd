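---
title: "Decomposing FLC silencing dynamics in field vernalization experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing FLC silencing dynamics in field vernalization experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vernadyn)
```

## The scientific problem

In *Arabidopsis thaliana*, prolonged cold silences the floral repressor
*FLOWERING LOCUS C* (*FLC*) -- the vernalization response that aligns
flowering with spring. In field conditions this shutdown proceeds in two
phases: an early, VIN3-independent transcriptional downregulation driven by
cool autumn temperatures, and a later, faster epigenetic (PRC2-mediated)
phase that begins once the cold-induced gene *VIN3* is substantially
upregulated. Natural accessions differ in their *FLC* haplotypes, and a
central question is which part of the silencing process that non-coding
variation actually changes: the level of *FLC* going into winter, the early
shutdown rate, or the epigenetic silencing rate.

vernadyn operationalises this analysis. Each genotype's normalized *FLC*
time course is decomposed into three features:

* **Starting level** -- mean *FLC* at the first field timepoint (note this
  is *not* a non-vernalized baseline: some VIN3-independent shutdown has
  already happened by the first sampling);
* **VIN3-independent rate** -- the regression slope of *FLC* on
  days-after-sowing over timepoints up to the *VIN3* induction day;
* **VIN3-dependent rate** -- the slope over timepoints after induction.

Downstream, the package compares these features across genotypes, asks
which feature is most variable, links *FLC* at transfer to subsequent
bolting time (the "post-vern" statistic), and models overwinter fitness.

## The model and its stages

### qPCR normalization and quality control

Expression values are relative starting concentrations from qPCR.
`normalize_to_references()` divides each target by the geometric mean of
the *PP2A* and *UBC* reference genes; `calibrate_to_control()` rescales a
series so a designated control sample (shared across plates and years)
equals exactly 1, which makes series from different batches directly
comparable and leaves within-plate ratios untouched.

`quality_filter()` implements two exclusion rules at the
technical-replicate level:

1. duplicate measurements whose Cq spread exceeds 0.6 cycles are dropped
   unless a retest is available;
2. a sample whose reference-gene Cq exceeds 28 (possible degradation) is
   excluded only when a target amplicon is *also* anomalous -- missing, or
   an order of magnitude (configurable fold 10) away from the median of
   the non-flagged samples of its genotype and timepoint. A high reference
   Cq alone only flags the sample.

The "anomalous" criterion needed operationalising: we read "varying by an
order of magnitude" as lying outside `[median/10, median*10]` of the peer
group, with the fold exposed as a threshold. Conversion from Cq uses
`conc = efficiency^(-cq)` with a per-run constant efficiency (default 2);
per-well efficiency estimation from raw fluorescence curves is upstream of
this package and out of scope.

### Breakpoint: the day of VIN3 induction

The induction day that separates the two fitting windows is estimated by
`detect_induction()`: baseline = median of the first 3 per-day means,
threshold = `max(3 * baseline, 0.05 a.u.)`, induction = first sampled day
whose mean exceeds the threshold for 2 consecutive timepoints. The
consecutive-exceedance requirement is deliberate: *VIN3* fluctuates
strongly with the temperature profile, and a single warm-spell spike
should not be mistaken for the onset of epigenetic silencing. Detection
failure is an explicit result (`detected = FALSE`), not an error, because
some mutants genuinely delay *VIN3*.

The rule itself is a design choice -- published induction days are
typically read from curves ("~58 days", "~48 days") without a stated
detection algorithm -- so the defaults (3 baseline points, 3-fold, 2
consecutive, 0.05 a.u. floor) were fixed once, before calibration, and the
absolute floor can be disabled to make detection fully scale invariant.
By default the breakpoint is estimated from the reference genotype
(Col FRI) and shared across genotypes at a site, because induction timing
is very similar between genotypes at the same site; any stage accepts a
fixed day instead.

### Decay features

`fit_phase_rate()` is ordinary least-squares of expression on day, with
replicates entering as individual points (so the same long table feeds the
mixed model). `extract_features()` applies it per phase window; the
breakpoint day itself belongs to the VIN3-independent window by default
(configurable). A trailing-day exclusion (e.g. 155 days) supports the
case where late-winter warming reactivates *FLC* and a decline model no
longer applies; in `"combined"` mode a single rate is fitted, which is the
right description when the two phases occur concurrently and a single
decline is seen.

**Linear vs log scale.** The field literature describes these declines as
"exponential decay" yet reports rates in a.u. per day as "the slope of the
fitted line", which is only dimensionally consistent with regression on
the linear scale. We therefore default to `scale = "linear"` and provide
`scale = "log"` as an option; on log-scale fits the slope is in /day and
all values in the window must be positive (hence the expression floor).

### Comparative statistics

* `dunnett_vs_control()` -- many-to-one comparisons of, e.g., starting
  levels against Col FRI. The family-wise adjustment is the
  equicoordinate probability that the maximum absolute contrast
  t-statistic exceeds the observed one, evaluated by seeded Monte Carlo
  (default 200,000 draws). We chose Monte Carlo over numeric integration
  for transparency and exact seeding; the per-contrast Monte-Carlo
  standard error is reported (about 1.1e-3 worst case at the default,
  about 5e-4 at `mc_draws = 1e6`). With a single contrast the adjusted
  p-value reduces to the pooled two-sided t-test.
* `mixed_slope_contrasts()` -- shutdown-rate comparisons via
  `lmerTest::lmer(value ~ genotype * day + (1 | block))` fitted by REML
  with the day covariate centred to mean 0, Satterthwaite denominator
  degrees of freedom for the interaction t-tests, and a documented
  fallback to fixed-effects regression when only one block exists.
* `cv_equality_test()` -- the asymptotic (Feltz-Miller) chi-square test of
  equal coefficients of variation, the statistic being the
  `(n_i - 1)`-weighted squared deviations of group CVs around the pooled
  CV divided by `cv^2 (0.5 + cv^2)`, with k - 1 degrees of freedom.
* `bh_adjust()` -- Benjamini-Hochberg step-up control at FDR 0.05.
* `variability_report()` -- the feature-variability comparison: CVs of
  genotype-level point estimates per site and year, tests of
  features-within-site and feature-across-sites, jointly BH-corrected.
  Rates enter as magnitudes, since variability rather than sign is being
  compared; CVs are computed over genotype-level estimates (not replicate
  values), matching how the feature panels are summarised, though callers
  can subset genotypes to reproduce accession-only or NIL-only analyses.

### The post-vern statistic

`fit_postvern()` regresses mean days-to-bolting on mean *FLC* at transfer
across transfer dates: `days to bolting = m * FLC + c`. The slope `m`
("FLC post-vern", days-to-bolting per FLC unit) captures how strongly
residual *FLC* delays flowering after return to warm, inductive
conditions -- plausibly reflecting reactivation propensity. Regression is
on genotype-level means per transfer date (a plant-level option exists via
the `flc_col` argument of `postvern_from_transfers()`); censored (DNF,
"did not flower") and dead plants are excluded with a reported count.
Two-point fits return the exact slope with the standard error explicitly
unavailable; fits with slope p > 0.1 are flagged unreliable; genotypes
whose *FLC* never rises above 0.05 a.u. are flagged as too low for
estimation (the Col-0 case); and genotypes with fewer than two observed
transfer dates yield an explicit "n.d." result (the Löv-1-in-the-North
case). Cross-site averages (`average_postvern()`) are taken on unrounded
values and only displayed half-up to one decimal (`round_half_up()`),
which is why a mean of 37.75 prints as 37.8.

### Fitness models

`precocious_bolting_model()` reports both summaries in routine use for
percentage data: the plant-level binomial GLM (logit) of bolting before
winter on autumn *FLC*, and the genotype-level linear R² of the bolting
percentage on *FLC* -- the two are complementary and both are emitted.
`survival_proportion_test()` reads "binomial proportions test" as the
two-proportion chi-square (score) test, with Fisher's exact test as an
option for extreme tables. `silique_models()` fits the genotype-level
regressions (survivor siliques ~ branches; branches ~ post-vern;
total siliques ~ post-vern + survival with adjusted R²) and reduces the
two-predictor model to a minimal adequate model by backward elimination
on p-values with every step logged -- elimination order is not prescribed
anywhere, so largest-p-first is our documented choice; near-collinear
predictors disable auto-reduction with a condition-number warning.
`rank_test()` is a Mann-Whitney U with midranks whose null distribution is
fully enumerated for combined n <= 20 (exact even with ties) and
tie-corrected normal otherwise.

## The synthetic-data generator

`simulate_expression()`, `simulate_transfers()` and `simulate_fitness()`
generate a complete field experiment with known ground truth, so every
stage is testable without external data. The generator mirrors the field
design: 6 replicate samples per genotype and timepoint in 3 randomised
blocks, 12 plants per warm transfer with a censoring horizon (default 205
days, after which plants are DNF), and 36 plants per genotype scored for
fitness.

The mean *FLC* trajectory is piecewise (linear by default, matching the
a.u./day rate convention; log-linear optionally), continuous at the
breakpoint and truncated at a floor of 0.01 a.u. (expression cannot be
negative, and the log-scale option needs positivity). Replicate noise is
multiplicative log-normal -- expression data are positive and
heteroscedastic -- with a log-scale block effect shared across genotypes
within a block, mirroring the block-randomised design. No replicate-level
noise magnitude is published for this kind of dataset, so the defaults
(noise SD 0.2, block SD 0.1 on the log scale) were chosen once for test
power rather than claimed realism. *VIN3* is simulated as a step: baseline
0.05 a.u. before the induction day, 1.5 a.u. after.

Bolting times are `m * FLC(t_transfer) + c` plus normal noise, floored at
one day; fitness outcomes follow logit models for precocious bolting
(decreasing in autumn *FLC*) and overwinter survival (penalised for
bolted plants, defaults set so the two survival arms are 67% and 42%),
with branch counts declining in the genotype's post-vern value and
silique counts Poisson in branches. The synthetic covariate recorded for
transfers and the autumn census is the *true* mean trajectory value (the
measured replicate mean is attached alongside when an expression table is
supplied); outcomes are generated from the same value, so recovery tests
have nominal coverage without an errors-in-variables correction.

What the generator does **not** emulate: temperature-driven *VIN3*
dynamics and its fluctuations (the induction day is a configuration
input, not a mechanistic output), *FLC* reactivation after midwinter
warming, germination/dormancy variation, spatial field heterogeneity
beyond block effects, and measurement error in the FLC covariate of the
transfer model. Passing recovery tests therefore demonstrate correctness
of the estimators under the stated generative model, not robustness to
every feature of real field data.

## Numerical choices and degenerate inputs

* Determinism: all generators draw through `withr::with_seed()`, so a
  configuration (including its seed) maps to byte-identical tables; the
  transfer and fitness stages use streams derived from `seed + 1` and
  `seed + 2` so the three tables are jointly reproducible from one seed.
* With multiplicative log-normal noise the mean of an observed value is
  the noiseless trajectory times `exp(sigma^2/2)`; calibration studies
  compare estimates against that shifted truth (e.g. a starting level of
  10 with noise SD 0.2 has observable mean `10 * exp(0.02)`).
* A phase window with fewer than two distinct days yields an explicit
  "unavailable" feature with a reason string, never a silent `NaN`; the
  155-day-style exclusion is recorded in the output.
* Dunnett adjusted p-values are clamped to be at least the raw t-test p
  (the family-wise invariant), which also makes the k = 1 case agree with
  the pooled t-test exactly.
* Zero residual variance (all groups constant) and zero FLC spread are
  errors or flagged results, as appropriate, with messages naming the
  offending group.
* `quality_filter()` is idempotent; retest records are exempt from the
  duplicate-spread rule so a retested pair survives a second pass.

## Problem sizes used in the test suite

The calibration studies in the tests and the acceptance script use 500
simulated seasons for coverage checks (6 replicates, 4 timepoints per
phase, log-noise 0.2), 2000 simulations for type-I error and family-wise
error calibration, and 1000 random p-vectors for the BH oracle
comparison. These sizes give Monte-Carlo standard errors of roughly half
a percentage point on coverage rates -- comfortably inside the >= 93%
acceptance bands -- while keeping a full run in the low minutes on a
single CPU.

## A worked example

```{r example, eval = FALSE}
gs <- list(
  genotype_params("Col FRI", starting_level = 10, rate_vindep = 0.10,
                  rate_vdep = 0.15, postvern_m = 36.5),
  genotype_params("Lov-1", starting_level = 20, rate_vindep = 0.10,
                  rate_vdep = 0.18, postvern_m = 60))
cfg <- simulation_config(gs, timepoints = c(20, 27, 34, 41, 55, 62, 69, 76),
                         breakpoint_day = 48,
                         transfer_days = c(27, 41, 62, 76), seed = 1)
sim <- simulate_expression(cfg)
res <- run_pipeline(sim$expression,
                    bolting = simulate_transfers(cfg),
                    fitness = simulate_fitness(cfg),
                    output_dir = tempfile("vernadyn-run-"))
res$features[, c("genotype", "starting_level", "rate_vindep", "rate_vdep")]
```

## Known limitations

* The decline model is piecewise linear (or log-linear); no nonlinear
  mixed-effects or smoothing alternative is provided.
* The asymptotic CV test is the only CV-equality test implemented; the
  modified signed-likelihood-ratio variant is out of scope.
* Unspliced *FLC* is carried through as just another gene column; no
  bespoke analysis is attempted for it.
* The Dunnett adjustment is Monte Carlo; p-values carry a quantified,
  seeded sampling error rather than quadrature precision.
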