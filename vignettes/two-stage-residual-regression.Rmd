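---
title: "Two-stage residual-outcome regression for DNAm biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage residual-outcome regression for DNAm biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiaccel)
```

## The problem

DNA methylation surrogate biomarkers — epigenetic age clocks, a telomere-length
estimator, cell-count surrogates, plasma-protein EpiScores — are all strongly
age-dependent. Comparing them between phenotype groups (here the motivating
setting is painful diabetic neuropathy, PDN, versus painless diabetic
neuropathy, PLDN, and healthy controls, CTRL) therefore confounds the group
effect of interest with ordinary chronological aging and with sex. `epiaccel`
implements a reference-group answer to this: fit the biomarker's normal
age/sex trajectory on one designated group only, then measure every sample as
a deviation from that trajectory.

## The model

For each biomarker $y$ the package fits, **on reference-group samples only**,

$$y_i = \beta_0 + \beta_1\,\mathrm{age}_i + \beta_2\,\mathrm{sex}_i + \varepsilon_i$$

by ordinary least squares (stage one), and then computes for **every** sample
— reference group included —

$$r_i = y_i - (\hat\beta_0 + \hat\beta_1\,\mathrm{age}_i + \hat\beta_2\,\mathrm{sex}_i)$$

(stage two). The residual $r_i$ is the sample's age- and sex-adjusted
deviation, in the biomarker's own units (years, for an age clock: positive
residuals mean epigenetic age acceleration relative to the reference group's
trajectory). Groups are compared on these residuals with two-sided
pooled-variance Student's t-tests at $\alpha = 0.05$; because the reference
fit contains an intercept, the reference group's mean residual is exactly
zero, so each contrast against the reference reads directly as a mean
acceleration difference.

Modelling choices worth stating explicitly:

* **Sex stays in the model** even when its coefficient is not significant; it
  is dropped only when the reference group is single-sex (rank deficiency),
  with a warning.
* **Equal-variance t-tests are the default** throughout, with the Welch form
  available behind a flag (`welch = TRUE`).
* **No multiple-testing correction by default**, matching a raw 0.05
  threshold per biomarker; `bh = TRUE` appends Benjamini–Hochberg q-values
  per contrast without altering the raw flags.

## Outlier handling

Before stage one, each biomarker is screened with Tukey fences: values below
$Q_1 - 1.5\,\mathrm{IQR}$ or above $Q_3 + 1.5\,\mathrm{IQR}$ are set to
missing for that biomarker only, so the sample still contributes to every
other biomarker. Three conventions are fixed and documented because they
change results:

* quartiles use linear interpolation between the closest order statistics
  (R's type 7) — other quantile definitions move the fences;
* fences are computed over **all samples pooled**, not per group (per-group
  fencing is available via `per_group = TRUE`); pooled fencing is the
  conservative reading when outliers are assumed to be technical artefacts
  rather than group-specific biology;
* exactly **one pass** is made. Re-fencing after removal can flag further
  points (the operation is not idempotent), and iterating it to convergence
  can chew arbitrarily far into a heavy tail.

## Quality control

`qc_filter()` applies the two standard detection-p rules in a fixed order:
samples with mean detection p-value above 0.05 are removed first, then probes
with a detection p-value above 0.01 in at least one *remaining* sample.
Both thresholds are strict inequalities. The order is part of the contract —
a probe that fails only inside an already-excluded sample is kept — and the
report lists every removal with its triggering statistic. The pipeline
consumes already-normalized beta values; raw-intensity processing and
normalization are out of scope. Betas outside $[0,1]$ are rejected rather
than clamped, since clamping silently hides upstream faults.

## The clock engine

All surrogate biomarkers are represented structurally, not numerically: a
`clock_definition` is a named weight vector over CpGs plus an intercept and an
output transform (`identity`, or the `horvath-inverse` anti-log calibration
with its adult-age knot, default 20 years). Published coefficient sets —
Hannum, Horvath skin-blood, PhenoAge, DNAmTL, EpiScores — can be loaded from
CSV + JSON sidecar files; none ship with the package (several are
proprietary). Three engine details:

* **PC clocks are pre-flattened.** A principal-component clock is a linear
  projection followed by a linear score, i.e. one linear map;
  `flatten_pc_clock()` collapses the two steps so no second coefficient
  format is needed.
* **Composite clocks** of the GrimAge family combine previously computed
  sub-biomarkers with age and sex: `intercept + sum(w_k * biomarker_k) +
  w_age * age + w_sex * sex`, with missing components propagating to a
  missing output.
* **Missing CpGs**: a clock CpG absent from the matrix is dropped from the
  sum (counted in the report); a CpG present but missing in some samples is
  imputed with the probe's cohort mean under the default
  `impute-cohort-mean` policy, or raises an error under `error`. Published
  calculators impute with training-set means; those means are unavailable
  for user-supplied clocks, so the cohort mean is this package's documented
  substitute, and the per-clock imputation count is reported so heavy
  imputation is visible.

Cell-type fractions are estimated by constrained projection: per sample,
non-negative least squares of the beta profile onto the reference panel,
followed by renormalization to the unit simplex. The pre-normalization sum is
retained; values far from 1 flag samples the panel explains poorly. An
equality-constrained quadratic program would be the textbook alternative; the
NNLS-then-renormalize route is deterministic, dependency-light, and agrees
with a grid-search oracle to well under the noise level in the test suite.

## The synthetic cohort generator

`generate_cohort()` produces cohorts with exactly the statistical structure
the analysis assumes, so every stage is testable against known ground truth:

* per sample, acceleration $a_i \sim N(\Delta_g, \sigma_a)$ defines an
  *effective age* $\mathrm{age}_i + a_i$;
* each probe's beta is linear in effective age
  ($\beta_{ji} = b_{0j} + s_j \cdot \mathrm{eff.age}_i + \mathrm{sex}_j
  \cdot \mathrm{sex}_i + \varepsilon_{ji}$, clipped to $[0,1]$ with the
  clipped fraction audited);
* detection p-values are tiny except for sporadic injected failures.

Acceleration is modelled **additively in years on an effective age**, which
makes the injected effect directly comparable to clock residuals: with the
matched toy clock (`generate_toy_clock()`, weights $1/(m s)$, intercept
$-b_0/s$) and zero noise, clock output minus chronological age equals each
sample's true acceleration exactly.

Defaults mirror a three-group neuropathy cohort for face validity: group
sizes 99/132/84 (PDN/PLDN/CTRL), ages uniform on 41–84 years, sex ratio 0.5,
$\Delta = (+3, 0, -2)$ years, between-individual acceleration sd 3 years,
probe noise sd 0.01 beta units, 50 CpGs, baseline $b_0 = 0.2$, drift $s =
0.005$/year. Real residual effect sizes in years are not published for the
motivating study, so the $\Delta$ values are test parameters chosen to be
detectable but not trivial at these group sizes. The detection-failure rate
defaults to $10^{-4}$ per cell: since probe QC removes a probe failing in
*any* sample, per-probe loss is $1 - (1-\mathrm{rate})^n \approx 3\%$ at
$n \approx 300$, matching a well-behaved processed array study.

Reproducibility is two-level: one seed for the sample-level draws, plus a
deterministic per-sample sub-stream for probe-level noise, so sample values
are invariant to the probe count and ordering.

What the generator deliberately does **not** emulate — real EPIC probe beta
distributions (bimodality), beadchip batch effects, cell-composition
confounding with phenotype, non-linear age trajectories. Passing tests
therefore demonstrate that the *procedure* is implemented correctly and
calibrated under its own assumptions, not that those assumptions hold in any
particular real cohort.

## Calibration and validation

The test suite validates the pipeline at three levels, all on synthetic
cohorts generated at run time:

* **Oracle equivalence** — on 25-sample cohorts, every residual, t, df, p,
  ANOVA F and Pearson r matches an independently written flat script
  (explicit order-statistic quantiles, normal equations, textbook test
  statistics) to $10^{-8}$.
* **Parameter recovery** — at group sizes 99/132/84 with $\Delta_{PDN} = +3$
  years and individual sd 3 years, the mean recovered PDN−PLDN residual
  difference over 100 seeded cohorts lies within ±1 year of 3 and the
  contrast is significant in ≥ 90 of 100 seeds.
* **Null calibration** — with all $\Delta = 0$, the empirical type-I error of
  the PDN–PLDN contrast over 400 seeded cohorts stays inside the exact
  binomial 99% interval around 0.05.

The same quantities are recomputed from scratch by `scripts/acceptance.R`.
These problem sizes (50 probes; 315-sample cohorts; 100 and 400 replicates)
were chosen so the full validation runs in well under a minute on one core
while keeping the binomial intervals tight enough to be meaningful.

## Worked example

```{r example}
cfg <- simulation_config(seed = 7)
cohort <- generate_cohort(cfg)
clock <- generate_toy_clock(cfg)

qc <- qc_filter(cohort$beta, cohort$detp)
sheet <- cohort$sheet[cohort$sheet$sample_id %in% colnames(qc$beta), ]
class(sheet) <- class(cohort$sheet)

biomarkers <- compute_biomarkers(qc$beta, sheet, list(clock))
trimmed <- remove_outliers(biomarkers)
stages <- two_stage_residuals(trimmed$table, sheet, "PLDN")
contrast_table(stages$residuals, sheet,
               list(c("PDN", "PLDN"), c("CTRL", "PLDN")))
```

The `mean_diff` column is the recovered group acceleration in years; with the
defaults it should sit near the injected +3 (PDN) and −2 (CTRL).

## Known limitations

* Covariate adjustment is fixed at age + sex; additional covariates in the
  sample sheet are carried but not modelled (no mixed models, no propensity
  adjustment).
* Stage-one uncertainty is ignored in stage two: residuals are treated as
  data in the t-tests, as is conventional for this design, which slightly
  understates variance when the reference group is small.
* The quantile convention, QC order, and single-pass fencing are fixed
  choices; alternatives change results and are deliberately not configurable
  beyond the documented flags.
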