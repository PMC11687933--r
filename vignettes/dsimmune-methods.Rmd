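---
title: "Methods: quantifying immune dysregulation in trisomy 21 cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying immune dysregulation in trisomy 21 cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsimmune)
```

`dsimmune` implements the statistical core of immune-dysregulation studies
in Down syndrome (trisomy 21, T21): autoantibody bead-array analysis,
composite interferon (IFN) and cytokine scores referenced to euploid (D21)
controls, beta regression on immune-cell compositions, mixed-model
differential abundance of plasma analytes, and longitudinal endpoint
evaluation for a JAK-inhibitor trial. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where a published analysis description leaves the details open.

## Autoantibody bead arrays

Raw median fluorescence intensities (MFI) from antigen bead arrays carry
strong sample-specific backgrounds (serum matrix effects, total IgG).
`mad_transform()` standardizes each sample over its antigens:

$$\mathrm{MADs} = \frac{\mathrm{MFI} - \mathrm{median}_{\text{sample}}(\mathrm{MFI})}
{\mathrm{MAD}_{\text{sample}}(\mathrm{MFI})}$$

The **raw** median absolute deviation is used (consistency constant 1, not
1.4826). The constant cancels nothing downstream — it rescales every
threshold — so it is an explicit, configurable argument rather than an
implicit convention. The transform is invariant to positive affine
rescaling of a sample's MFI, which is exactly the class of nuisance it is
meant to remove. Samples with zero MAD (constant MFI) are rejected by name;
wells under 20 beads (configurable) are treated as missing.

Positivity for each antigen is a strict exceedance of the 90th percentile
(type-7, linear interpolation; configurable) of the **euploid control**
MAD values. By construction at most $10\% + 1/n_{\text{controls}}$ of
controls can be called positive per antigen. Antigens detected in fewer
than 18 samples are excluded; "detected" is read as "called positive"
(the most conservative reading), with a `count = "measured"` alternative
for the non-missing-well reading.

Group enrichment uses Fisher's exact test per antigen (two-sided by
default; `alternative = "greater"` tests pure overrepresentation), with
Benjamini–Hochberg (BH) correction and significance at q < 0.1 throughout
the package. Odds ratios are cross-products with a Haldane 0.5 correction
when a cell is empty, so reported effect sizes are always finite.
Condition associations within the T21 group skip conditions with fewer
than five cases.

Two scalar assays complete the module: the anti-TPO index
$(\text{signal} - \text{neg})/(\text{pos} - \text{neg})$ thresholded at
the 95th percentile of healthy-control indices, and the ANA OD ratio
called positive at $\ge 2.1$ (the kit convention; the boundary value is
positive).

## Composite IFN and cytokine scores

Both composite scores are sums of per-feature Z-scores. Two
standardization modes are recorded explicitly:

* **reference** — Z computed from the mean and SD of the adjusted euploid
  control samples. The reference group's own score then centers on zero
  and cohort members are expressed in "euploid SDs".
* **internal** — Z computed across the compared sample set itself. For
  trial data all timepoints are pooled into the standardization set; a
  baseline-only standardization is available by subsetting before calling
  `internal_zscores()`. Pooling is the default because the comparison of
  interest is across timepoints within the same set.

Nuisance covariates (age, sex, batch/sample source) are removed by
per-feature least squares (`fit_covariate_adjustment()` /
`apply_adjustment()`): the design includes the biological grouping so the
nuisance coefficients are not contaminated by group differences, and only
the nuisance part is subtracted, centered at reference covariate values
(numeric covariates at their mean, factors at their first level). This is
the same operation as limma's `removeBatchEffect` up to a per-feature
constant, which the test suite verifies.

The ISG panel is selected from a differential-expression table: candidates
with fold-change $\ge$ 1.5 (the boundary qualifies) and q < 0.1,
excluding *IFNAR2*, *MX1* and *MX2*, whose elevation reflects chromosome-21
dosage rather than interferon signalling. Expression values are
transformed as $\log_2(\mathrm{FPKM} + 1)$ before adjustment and Z-scoring;
the offset keeps low-expression genes finite and stabilizes variance. A
raw-FPKM path can be had by passing the untransformed matrix.

Group comparisons report the median difference with a Mann–Whitney U
p-value (exact when both groups have at most 12 observations and no ties;
otherwise midranks with tie-corrected variance and continuity correction).
Paired trial comparisons use the two-sided Wilcoxon signed-rank test,
exact for at most 15 non-zero differences, zeros dropped, BH-corrected
across the family of endpoints.

## Compositional immunophenotyping

Cluster relative frequencies live in (0, 1) and are heteroskedastic, so
inference uses a mean–precision beta regression with a logit link:
$y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$,
$\mathrm{logit}(\mu) = \mathbf{x}^\top\beta$, with a single constant
precision $\phi$ (the published description names only a mean submodel).
The fit is maximum likelihood via BFGS on $(\beta, \log\phi)$ with
analytic gradients, started from a logit-scale least-squares fit and a
method-of-moments precision; standard errors come from the inverse
observed information and coefficient tests are Wald. The suite checks the
optimum against a brute-force grid search and verifies null calibration
and parameter recovery by simulation.

Because the link is logit, $\exp(\beta_{\text{group}})$ is an **odds-scale**
fold-change. Results tables therefore carry both `fold_change` =
$\exp(\beta)$ (the conventional report) and `mean_ratio`, the implied
ratio of fitted means at reference covariates, to prevent misreading for
non-rare clusters.

Extreme outliers are masked per karyotype and cluster before fitting:
values more than 3 interquartile ranges beyond the quartiles (type-7).
Equality with a fence is not an outlier, constant groups mask nothing,
and groups under 4 observations are skipped with a warning. Observed 0/1
proportions are compressed by $y' = (y(n-1) + 0.5)/n$ before the beta
likelihood is evaluated. Masking precedes compression and fitting. BH
correction is applied within a gating level (live, CD45+CD66lo, T, B),
not pooled across levels; pooling can be had by passing all fits to
`summarize_fold_changes()` at once.

## Plasma analytes and mixed models

Multiplex immunoassay concentrations arrive as duplicate wells with
detection-range flags. Preprocessing replaces out-of-range wells with the
minimum (below) or maximum (above) **in-range calculated concentration on
the same plate** — deliberately not the assay limits, which would inject
values never observed on that plate — then averages replicates. Zero or
negative calculated concentrations are treated as below range so
$\log_2$ is always defined. Analytes with strictly more than 10% of wells
out of range are flagged; plates with no in-range well for an analyte are
dropped for that analyte with a report.

Differential abundance fits, per analyte,
$\log_2(\text{conc}) \sim \text{group} + \text{age} + \text{sex} +
(1\,|\,\text{source})$ by REML. "Sample source" is an arbitrary grouping
column (collection site, assay batch — whatever the data provide). When
the random-intercept variance is estimated at zero the fixed effects
coincide with ordinary least squares, which the tests verify; a single
grouping level falls back to a fixed-effects fit with a warning.
P-values default to Satterthwaite degrees of freedom (the convention of
the lmerTest fitter used in this field); a normal Wald approximation is
available via `df_method = "wald"` and is indistinguishable at cohort
sample sizes.

The age-versus-karyotype decomposition tests each analyte twice — the
karyotype effect from the mixed model, and the age slope within the T21
group from a simple linear regression — BH-corrects each family
separately, and classifies analytes as `T21 only`, `age only`, `both` or
`ns` at q < 0.1.

## Trial endpoints

Endpoints are evaluated against baseline (week 0): a participant counts
as decreased only for a strictly negative change, so exact ties are
conservative. The upper-limit-of-normal (ULN) response logic identifies
participants strictly above the ULN at baseline (anti-TPO 60 U/mL,
anti-TG 4 IU/mL by default), counts decreases among them at weeks 8 and
16 — the "both weeks" summary requires both visits present — and reports
who reached the ULN or below at any on-treatment visit. The safety rule
passes when at most two serious adverse events are definitely attributed
to the drug. Week-40 extension data are carried but excluded from 16-week
endpoints by default, and endpoint q-value display can be suppressed to
mirror interim-analysis reporting rules.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
participant-level data. Its defaults encode the emulated study design:
120 T21 and 60 D21 participants in the array arm; T21 condition
prevalences of 53.1% (autoimmune thyroid disease), 43% (immune skin
conditions) and 9.6% (celiac disease); a 54-analyte plasma panel with
log-normal concentrations, T21 fold-changes on the cytokine-score
analytes, plate and source effects, and detection limits that censor a
few percent of wells; a 16-gene ISG panel with T21 fold-changes spanning
1.5–3 plus chromosome-21 decoys and null genes; a 10-cluster
logistic-normal composition with odds-scale T21 shifts (B-cell-like
depletion, TEMRA-like and basophil-like enrichment); and a
10-participant trial over weeks 0/2/8/16 with multiplicative treatment
effects and optional immune-trigger spikes. Where the emulated study
reports no distributional forms, the choices here (log-normal signals,
normal effects on log scales, logistic-normal compositions) are the
standard generative models a biostatistician would reach for, and they
are fixed once in the defaults rather than tuned per analysis. The trial
anti-TPO baseline distribution is set so that about seven of ten
participants start above the 60 U/mL ULN, matching the emulated trial
population's thyroid-autoimmunity burden.

Design choices worth knowing:

* One root seed spawns fixed per-table RNG substreams, so adding a table
  to a bundle never perturbs the draws of another.
* Censoring is recorded as below/above-range flags with missing values,
  never clipped numbers, so the imputation path is always exercised.
* Plates, sources and sequencing batches are assigned randomly across
  karyotypes, as in the assayed cohort; a confounded design can be built
  by editing the returned tables.
* Positivity ground truth is retained (`$truth`) for recovery testing.

What the generator does **not** emulate: raw cytometry events or gating,
sequencing reads, bead-level array images, antigen cross-reactivity,
longitudinal cohort visits, or missingness mechanisms beyond detection
limits. Passing tests therefore demonstrate that the estimators recover
the structure this generator produces — group effects under covariate
noise, censoring, and batch structure — not that they are robust to every
pathology of real cohort data.

## Calibration and recovery evidence

The test suite (and `scripts/acceptance.R`) recomputes, from scratch:

* exact-test oracle equivalence (Fisher vs hypergeometric enumeration on
  all 2×2 tables with totals ≤ 20 plus sampled tables to 40; Mann–Whitney
  and signed-rank vs full enumeration at n ≤ 10; BH vs direct step-up);
* null calibration at 200 replicates per family — Fisher enrichment is
  conservative (discrete p-values, upper bound), while the beta-regression
  and mixed-model families reject within exact binomial 99% bounds of the
  nominal 10% FDR level;
* parameter recovery — $\beta_{\text{group}} = 0.5$ within ±0.1 at
  n = 500, $\phi = 50$ within 20%; a 1.0 log2 group effect within ±0.15
  at n = 400 with four sources; an ln(2) composition shift recovered as a
  fold-change in [1.7, 2.3] at n = 300; and T21/D21 separation of the
  composite IFN score at p < 0.01 with 100 per group.

Replicate counts and sample sizes in these checks are the package's own
choices, set to make the binomial bounds informative while keeping the
default test run fast.

## Configuration and orchestration

`run_pipeline()` executes simulate → autoantibodies → scores → analytes →
composition → trial, writing every intermediate table as TSV (the
canonical dialect; CSV accepted on read) plus a JSON manifest with the
package version, seed and stage timings. Run configuration is a YAML file
read by `load_config()`; YAML was chosen because it is the configuration
format R tooling reads natively, and all randomness flows from the single
`seed` key. Readers validate each table against a named schema and report
problems by column and row. The exported functions are the interface;
`scripts/acceptance.R` shows a complete scripted run.

## Known limitations

* The beta regression uses a constant precision; precision covariates are
  out of scope.
* Satterthwaite degrees of freedom come from lmerTest; the `"wald"`
  option is a normal approximation, not a Kenward–Roger correction.
* Fisher enrichment treats antigens independently; correlated antigens
  (fragments of the same protein) share no information.
* The display adjustment (`adjust_for_display()`) is for plotting only;
  inference always runs through the models themselves.
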