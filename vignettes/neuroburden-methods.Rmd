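---
title: "Methods: secondary-injury prognostics and DALY accounting in neurocritical care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secondary-injury prognostics and DALY accounting in neurocritical care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroburden)
library(dplyr)
```

This vignette is the package's account of its models and the design
choices behind them: what is computed, under which assumptions, which
knobs matter, and what the synthetic-data tests do and do not
demonstrate about real cohorts.

## The clinical setting

One admission row describes an adult ICU patient with one of ten primary
acute neurological diagnoses, their admission severity scores (GCS,
APACHE II, SAPS III, SOFA), insurance coverage and admission type, six
chronic comorbidities, an admission physiology snapshot, and the 30-day
outcome: vital status, modified Rankin Scale (mRS), and ICU length of
stay capped at the 30-day observation window. Two codings anchor every
analysis:

* **Mortality.** Death in the ICU versus everything else (discharge,
  transfer, still hospitalised at day 30). Folding transfer and
  continued hospitalisation into the non-death arm makes the mortality
  denominator the full cohort, which is what keeps the univariate
  odds-ratio table internally consistent.
* **Unfavourable outcome.** mRS 4, 5 or 6. Patients with missing mRS are
  excluded from mRS-based analyses and counted, never imputed.

## Secondary-injury (Hs) classification

Ten threshold rules define the potential secondary injuries
(`hs_definitions()`). Three conventions are load-bearing and tested:

1. **Strict inequalities.** Every rule uses the printed `<` / `>`
   direction, so a value exactly at its cut-off (MAP = 65 mmHg,
   temperature = 37.5 °C, PaCO₂ = 35 or 45 mmHg, sodium = 135 mmol/L,
   glucose = 60 mg/dL, ICP = 25 mmHg) is negative.
2. **Missing is "not assessed".** A flag needs an observed abnormal
   value; a missing field can never fire one. A snapshot with no
   measurements at all classifies as zero injuries with an explicit
   warning rather than an error, because unmonitored patients are a real
   phenomenon.
3. **Herniation is clinical.** It is a recorded clinical judgement, not
   a rule computed from other fields.

The count of flags is partitioned into the reporting categories
zero / one / two / three-plus. The classifier is validated against an
independent scalar re-implementation of the rules on 10,000 random
snapshots that deliberately over-sample values at and adjacent to every
threshold, and a property test checks monotonicity: pushing any single
measurement further past a threshold it has already crossed never
removes a flag.

## Univariate and multivariable prognostics

For a 2×2 exposure-by-event table with cells *a, b* (exposed) and
*c, d* (reference), `odds_ratio()` returns the cross-product estimate
*ad/bc* with the Wald interval
$\exp(\log\widehat{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$ and
the Wald p-value. A zero cell is an error by default — degenerate strata
should be seen, not smoothed — with the Haldane +0.5 correction behind
an explicit flag.

`fit_logistic()` implements the multivariable counterpart by
iteratively reweighted least squares: Newton–Raphson on the Bernoulli
log-likelihood, coefficients initialised at zero, iterated until the
relative change in log-likelihood falls below 1e-10 (at most 100
iterations), with step-halving if a full Newton step overshoots.
Standard errors come from the inverse observed information at the
optimum; odds ratios are `exp(coefficient)` with Wald intervals
throughout (no profile likelihood). Perfect separation is declared when
any coefficient passes |30| — on the odds scale that is beyond anything
estimable from cohort data — and is an error by default or a flagged
result inside the model suite. The fitter is cross-checked against
`stats::glm` in the tests (coefficients, standard errors and
log-likelihood to 1e-6); `glm` is the oracle there, never the
implementation.

Four model specifications are run per outcome, each on its own complete
cases with dropped-row counts reported: (1) age, male sex, GCS, Hs
category versus zero, public versus private insurance, emergency versus
elective admission; (2) sex, APACHE II, insurance, admission; (3) sex,
SAPS III, insurance, admission; (4) age, sex, SOFA, insurance,
admission. Model discrimination is the rank-based (Mann–Whitney) ROC AUC
of the fitted probabilities, ties counted one half; it equals brute-force
pair counting on every instance, which the tests verify directly.

`chi_square_homogeneity()` wraps the Pearson statistic (no continuity
correction). In pairwise mode each pair of rows is compared on the 2×c
subtable formed by subsetting those rows (columns that become empty are
dropped), with Bonferroni adjustment over all row pairs. Subsetting —
rather than re-partitioning the full table — is a declared convention;
both readings exist in practice and the choice is documented here so the
adjusted p-values are interpretable.

## The DALY engine

Burden is `DALY = YLL + YLD`, computed per patient and summed.

**YLL.** Each death contributes the residual life expectancy $e_x$ at
the sex and integer age (floor) of death, looked up in a complete
single-year life table covering ages 18–110. No abridged-table
interpolation is performed — the engine expects a complete table, which
keeps the lookup exactly testable. The bundled table
(`synthetic_life_table()`, also shipped as
`inst/extdata/life_table_synthetic.csv`) is synthetic: a
Gompertz–Makeham hazard per sex tuned to life expectancies at birth of
72.8 (male) and 79.9 (female) years, the order of magnitude of recent
Brazilian period tables. Real analyses should supply the official
national table via `read_life_table()`.

**YLD.** Each survivor contributes
`combine_weights(mRS weight, comorbidity weights) × horizon × prevalence scaling`.
The disability weight of the functional state is selected by mRS level
(level 0 fixed at 0); the bundled synthetic map uses the published
sequela weights commonly applied to stroke severity levels for mRS 1–5
and plausible chronic-disease weights for the six comorbidities — which
weights a given study assigned to each mRS level is generally not
recoverable from published reports, so the map is an explicit input,
not a constant. Comorbidity correction multiplies on the *healthy
complement* scale, $w = 1 - \prod_i(1 - w_i)$, the standard
burden-of-disease convention for co-occurring states: order-invariant,
bounded below 1, never below the largest component and never above the
sum. Because "multiplying the weights" can also be read literally, the
raw product $\prod_i w_i$ is available as `method = "product"` for
sensitivity analysis; it is not the default.

**Horizon.** Published prevalence-based YLD figures rarely pin down the
time each survivor is counted as living in the state. The horizon is
therefore an explicit parameter: 1 year by default, `30/365.25` to
restrict to the 30-day follow-up window. YLD scales linearly in it and
YLL is untouched, which the tests assert.

**Prevalence.** Population meta-regression tools (DisMod-MR-class
Bayesian models) are out of scope for a self-contained package. The
stand-in, `estimate_prevalence()`, is a transparent beta-binomial
shrinkage estimator of within-cohort diagnosis composition per
sex × 5-year age band: a Beta prior of configurable strength (default
pseudo-count 2) centred at the pooled diagnosis rate shrinks sparse
strata toward the cohort rate; empty strata return the prior mean,
flagged. It is documented as *not* a population meta-regression: its
output scales YLD contributions by cohort composition, and headline
burden totals published from such tools are not reproducible from a
cohort table alone — the engine is validated instead by its accounting
identities and a five-patient hand-computed fixture.

Stratified outputs (by diagnosis, 5-year age band, age band within sex,
and Hs category) are sums of the same per-patient ledger, so they
reconcile with the totals exactly rather than approximately.

## The synthetic cohort generator

The generator exists so that every stage — classification, model
fitting, burden accounting — can be exercised and calibrated without
patient-level data. Its defaults are frozen to the marginal structure of
the motivating 1194-patient cohort:

* diagnosis mix proportional to the published group sizes
  (317, 218, 211, 155, 91, 77, 70, 25, 19, 11);
* group-wise age means/SDs, male proportions, and Hs-category
  distributions; cohort-level comorbidity prevalences, public-insurance
  probability 0.495, emergency-admission probability 0.734;
* missingness matching the published footnotes: 35/1194 SAPS III,
  54/1194 SOFA, 7/1006 survivor mRS.

Where only a median and IQR are published (GCS, APACHE II, SAPS III,
SOFA, length of stay) no distributional family is identified; the
generator's families are declared conventions, not inferences: severity
scores are latent normals matched to the median and IQR, discretised
onto the integer lattice and clamped to the legal range (the clamp at
GCS 15 produces the realistic ceiling-heavy shape), and length of stay
is a log-normal matched to the median and quartile ratio, capped at 30
days. Ages are truncated normals at 18, the study's inclusion bound.

**Hs-consistent physiology.** Each patient first draws an Hs category,
then a flag count (three-plus maps to 3–5), then the identity of the
flags weighted by the cohort-wide marginal Hs frequencies, with
hyper-/hypothermia and hyper-/hypocapnia kept mutually exclusive (they
share a measurement; the hypercapnia-via-bradypnoea route could co-occur
with hypocapnia but the generator does not produce that corner), and
finally physiology values strictly past the threshold for flagged
injuries and strictly on the safe side otherwise — including realistic
missingness (blood gas absent in ~35% of patients with no gas-dependent
flag, ICP only present when monitored). By construction `classify_hs()`
maps the generated snapshot back to the generated category for every
patient, and a test asserts exactly that.

**Outcomes.** Death is Bernoulli in a logistic model whose default
log-odds are the adjusted odds ratios of the first prognostic model,
with the intercept calibrated once so the default cohort mortality is
188/1194; all coefficients are configurable. Survivor mRS is allocated
by a proportional-odds rule on a second linear predictor, with
thresholds centred at run time against the published survivor mRS
margins — those margins are a calibration goal of the default spec, not
an invariant. Deaths are mRS 6 by construction.

**RNG design.** Draws are column-wise and vectorised under a single
seed, so a cohort is a deterministic function of its spec (tested), and
50,000-patient fidelity checks and 100 × 20,000 recovery replicates stay
cheap. The alternative — one counter-split stream per patient, so that
extending a cohort leaves earlier patients unchanged — was considered
and rejected: it costs an order of magnitude in generation time, and
the package's use cases regenerate whole cohorts from a spec rather
than append to them.

**What passing tests show.** Marginal fidelity (within 2 percentage
points at n = 50,000), parameter recovery (nominal CI coverage of
configured effects at n = 20,000), and null calibration (type-I error
5% ± 1% over 2,000 replicates of n = 500; null AUC 0.50 ± 0.02 at
n = 10,000) demonstrate that the *pipeline* is correct and calibrated
under the generator's assumptions. They do not validate those
assumptions against real data: the generator has no between-site
heterogeneity, no seasonality, no day-by-day physiology trajectories,
independent comorbidities, and a correctly-specified outcome model —
real cohorts guarantee none of these. Published adjusted odds ratios
and AUCs from real data are therefore structural templates here, not
test targets.

## Numerical conventions and degenerate inputs

* IRLS: tolerance 1e-10 on relative log-likelihood change, max 100
  iterations, zero initialisation, step-halving, separation at |β| > 30.
* Wald z throughout; `qnorm(0.975)` (not 1.96) in every interval.
* Print precision in report tables is frozen — percentages to 1 decimal,
  OR/CI to 3 — so golden-file diffs are meaningful. Published tables
  themselves round inconsistently in the third decimal, so printed-value
  comparisons in the tests allow one unit in the last printed digit.
* Degenerate inputs fail loudly with classed conditions
  (`nb_schema_error`, `nb_validation_error`, `nb_domain_error`,
  `nb_degenerate_error`, `nb_separation_error`, `nb_config_error`):
  zero 2×2 cells, zero table margins, constant outcomes, ages outside
  the life-table domain, weights outside [0, 1), survivors with missing
  mRS (excluded and counted), empty prevalence strata (prior mean,
  flagged).
* AUC ties count one half; complete-case handling is per model, with
  dropped rows reported, never imputed.

## Problem sizes used by the test suite

The suite runs the calibration studies at the sizes named above —
2,000 null replicates of n = 500, one n = 50,000 fidelity cohort,
100 recovery replicates of n = 20,000 — which keeps the whole suite
under a few minutes on one CPU while leaving Monte-Carlo error well
inside the asserted bands. The same computations, re-seeded from the
command line, are what `scripts/acceptance.R` writes out as JSON.

## Interfaces

The package is function-first: tibble in, tibble out, composable with
the pipe; `simulate → classify → fit → burden` is four calls
(`generate_cohort()`, `classify_hs()`, `run_model_suite()`,
`compute_dalys()`), and `write_cohort()` / `read_cohort()` fix a
bit-exact CSV dialect (UTF-8, comma, `.` decimal, snake_case headers,
empty cell = missing) for interchange. Report tables
(`report_descriptives()`, `report_univariate()`) and `write_report()`
with its provenance header cover scripted use; `scripts/acceptance.R`
is the runnable end-to-end entry point.
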