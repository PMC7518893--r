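# vernadyn

Decomposition and analysis of *FLC* silencing dynamics in field
vernalization experiments with *Arabidopsis thaliana*.

## What it is for

Over autumn and winter, cold represses the floral repressor *FLC* in two
phases: a slow, VIN3-independent transcriptional shutdown, followed by a
faster epigenetic silencing phase that starts once the cold-induced gene
*VIN3* is substantially upregulated. Natural *FLC* haplotypes differ in
how they traverse this process, with consequences for flowering time,
survival and seed set. vernadyn gives researchers working with such
field time-course data a tested pipeline from qPCR quality control to
fitness models.

Per genotype, site and year, each normalized *FLC* time course
`E(t)` (a.u., days after sowing) is decomposed around the site-level
VIN3-induction day `T*` into three features:

* starting level `S = mean E(t_first)`;
* VIN3-independent rate: OLS slope of `E` on `t` for `t <= T*` (a.u./day);
* VIN3-dependent rate: OLS slope for `t > T*`,

with a single combined rate when the phases occur concurrently. Downstream
statistics follow field practice: ANOVA with Dunnett many-to-one contrasts
against the reference genotype (seeded Monte-Carlo equicoordinate
adjustment), REML mixed-model slope contrasts
(`value ~ genotype * day + (1 | block)`, Satterthwaite t-tests), the
asymptotic (Feltz–Miller) test for equality of coefficients of variation
with Benjamini–Hochberg control, the post-vernalization statistic
`days to bolting = m [FLC] + c` (the slope `m`, "FLC post-vern", in
days-to-bolting per FLC unit), and binomial/Poisson GLMs linking autumn
*FLC* to precocious bolting, survival, branching and silique production.
A synthetic field-experiment generator with known ground truth makes
every stage testable end to end.

## A worked example

```r
library(vernadyn)

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

res$breakpoint
#> VIN3 induction detected at day 55 (baseline 0.0477, threshold 0.143)
res$features[, c("genotype", "starting_level", "rate_vindep", "rate_vdep")]
#>   genotype starting_level rate_vindep rate_vdep
#> 1  Col FRI           8.55      -0.125    -0.133
#> 2    Lov-1          18.82      -0.174    -0.221
res$postvern[["Col FRI"]]
#> FLC post-vern fit [Col FRI]: m = 36.8, c = 18.66 (n = 2; two points: no standard error calculable)
res$postvern[["Lov-1"]]
#> FLC post-vern fit [Lov-1]: m = NA, c = NA (n = 0; fewer than 2 transfer dates with observed bolting (n.d.))
```

Reading the output: induction is detected at day 55, the first sampled
day after the true switch at day 48 (sampling is roughly weekly, so
detection is resolved to one interval). The slopes are in a.u. per day
and negative for decline; the noisy estimates sit around the generating
values (0.10/0.15 and 0.10/0.18) and the starting level is the mean at
the first field timepoint (day 20), below the day-0 parameter because
shutdown is already under way. For Col FRI only the two late transfers
bolt within the 205-day follow-up, so its post-vern slope comes from two
points and carries no standard error; the high-*FLC* genotype never bolts
within follow-up at two or more transfer dates, so its slope is reported
as n.d. -- both situations occur in real transfer experiments and are
flagged rather than silently dropped.

All stage outputs (features, comparisons, variability report, post-vern
table, fitness models, provenance manifest) are written as CSV/JSON to
`output_dir`; `run_pipeline_config("config.yaml")` drives the same run
from a YAML file.

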