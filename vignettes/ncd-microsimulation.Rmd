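---
title: "Methods: NCD microsimulation and cost-effectiveness in ncdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NCD microsimulation and cost-effectiveness in ncdsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdsim)
```

`ncdsim` is an individual-level, annual-cycle state-transition model of five
major non-communicable diseases — cardiovascular disease (CVD), type 2
diabetes, asthma/COPD, breast cancer and colorectal cancer — in the adult
(40+) population of Gaza, with DALY accounting, intervention scenarios,
costing and probabilistic uncertainty. This vignette is the package's
account of its science: the model and its assumptions, the parameters that
matter, the numerical choices, and what the tests do and do not establish.

## The synthetic population

The survey that anchors the model (4,576 adults aged 40–80, 54.0% women,
with laboratory values in a 1,938-record subset) is not publicly deposited,
so the package ships a generator rather than data. It emulates:

* **sex-stratified marginals** — age, SBP and BMI as moment-matched
  truncated normals; diagnosis, medication, smoking and waterpipe flags as
  Bernoulli draws at the survey prevalences; the lipid panel, creatinine
  and HbA1c likewise per sex;
* **dependence** — a Gaussian-rank (latent normal) construction: all
  variables derive from one correlated latent normal vector per individual,
  continuous variables by inverse-CDF transform, booleans by thresholding at
  the prevalence quantile. Marginals are therefore exact in expectation
  whatever the dependence matrix. The default matrix encodes only
  relationships the survey context implies (age raises diagnosis prevalence
  and SBP; adiposity raises diabetes/hypertension/dyslipidemia; smoking
  concentrates with waterpipe use and respiratory disease; lipid fractions
  co-vary). It is fully replaceable via `population_spec()`.
* **treatment conditional on diagnosis** — medication flags are drawn among
  the diagnosed at the survey treatment rates (about 95% for diabetes and
  hypertension, 79.6% statin use among dyslipidemia), so `rx` implies `dx`
  by construction;
* **the lab subset and imputation** — `induce_lab_missingness()` blanks the
  whole lab block completely at random at the survey fraction (1938/4576);
  `impute_missing()` restores it by chained per-variable regressions with
  predictive-mean-matching donors, five chains pooled by averaging (a
  regression-tree conditional model is available via `method = "cart"`).
  PMM guarantees imputed values stay inside the observed range, and pooled
  averages inherit that; observed records are returned bit-exactly.

Choices worth flagging. Age is stored as integer years in [40, 80]; the
latent truncated normal is moment-matched so the published mean/SD survive
truncation. Blood pressure is a single SBP value (the survey's three
readings collapsed to their mean, the only published summary). HbA1c is
generated conditional on diabetes diagnosis (sex-specific means 13.3/11.5%
among the diagnosed); for the non-diagnosed, where the survey is
uninformative because testing concentrated on diabetics, we use 5.6% (SD
0.7), a standard non-diabetic value. Waterpipe use is generated but feeds
no risk score: cigarette smoking is the modeled exposure. There is no
household/cluster hierarchy and no survey weighting.

What passing generator tests show: the marginals and the encoded dependence
directions are recovered at survey scale. What they do not show: that the
*unpublished* joint structure of the real survey is reproduced — any
downstream quantity that depends on unmodeled interactions inherits that
uncertainty. Calibration (below) deliberately absorbs much of it.

## Risk scores and calibration

Each condition has an annual hazard from a published score family, shipped
as a replaceable coefficient fixture (`inst/extdata/risk_coefficients.json`):

* **CVD** — a Globorisk-style laboratory score (age, sex, SBP, total
  cholesterol, smoking, diabetes) computed per country baseline for Jordan,
  Lebanon and Syria; the three 10-year risks are averaged *in probability
  space* and converted to an annual hazard by `h = -log(1 - p10)/10`.
* **Diabetes** — FINDRISC categorical points mapped to the published
  10-year risk bands. Waist circumference is not surveyed, so the BMI band
  carries the waist points (a documented mapping); unsurveyed items
  (activity, diet, glucose history, family history) sit at their
  population-average zero points.
* **Asthma/COPD** — baseline age hazard x smoke-exposure rate ratio
  (active and second-hand exposures multiply).
* **Breast cancer** — Gail-style age baseline x relative-risk multipliers,
  women only; family-history inputs default to RR 1 (unsurveyed).
* **Colorectal cancer** — CRC-PRO-style multiplicative model (age, sex,
  smoking, obesity).

Because the published coefficient tables are not reproduced here, the
coefficients act as *relative-risk shapes*: `calibrate()` solves one
multiplicative hazard scale per condition so the expected 10-year cumulative
incidence per 10,000 matches its burden target, then one case-fatality scale
for the mortality target with the incidence scale held fixed. Aggregate
targets get a single global scale; age/sex gradients ride on the scores.

**Numerical choice — the calibration objective.** The objective is a
deterministic mean-field expectation, not a stochastic re-simulation: for
each individual the model propagates the probability of being alive and the
marginal probability of carrying each condition through the same annual
cycle as the engine. Survival treats conditions as independent within an
individual, and condition prevalence is *depleted among survivors* each year
(cases die faster than non-cases; without this depletion the case-fatality
scale for high-fatality cancers calibrates visibly low). The mean-field
objective is smooth and exactly monotone in the scale, so 50-iteration
bisection (relative tolerance 2%, bracket auto-expansion, explicit errors
for unreachable targets) converges without a Monte-Carlo noise floor. A
stochastic common-random-number objective (`objective = "simulation"`)
remains available as a cross-check; the test suite verifies that the
stochastically simulated baseline lands inside the targets' 95% intervals
in at least 4 of 5 seeds per condition.

## The simulation engine

One-year cycles over a 10-year horizon (both configurable). Within a year:

1. **Mortality first**, by competing exponential event times: every
   contending cause — per-condition case fatality among prevalent cases and
   Gompertz other-cause mortality fitted to the shipped life table — draws
   `T_k = -log(U_k)/h_k`; the individual dies if `min T_k <= 1`, and the
   cause is the argmin. This reproduces the closed form
   `P(death) = 1 - exp(-sum h)`, `P(cause k | death) = h_k / sum h` exactly
   (verified against that closed form at 2x10^5 draws).
2. **Incidence among survivors**, per condition not yet active, at
   `1 - exp(-s_c h_c)` with the cohort aged one year.
3. **Accrual**: disability years and intervention costs.

Prevalent disease at baseline is seeded from the survey diagnosis flags
(diabetes, asthma/COPD); CVD and the cancers start incident-only. Prevalent
cases accrue disability from year 0 and face case fatality but do not count
as incident.

**DALYs.** `DALY = YLD + YLL` with discrete annual discounting at 3% for
both dollars and DALYs (configurable; an undiscounted column is always
reported alongside). YLD weights each year lived with a condition by its
GBD-style disability weight (shipped, replaceable fixture): the onset year
counts in full and the death year at half — the half-cycle correction is
applied to deaths only, so that a condition held from year 0 over a 10-year
horizon accrues exactly `dw x annuity(10, 3%) = dw x 8.7861`, the package's
frozen discounting contract. YLL at a condition-attributed death is the
discounted remaining life expectancy at the age of death, interpolated from
the life table and discounted back to the death year. Other-cause deaths
accrue no condition DALYs.

No Palestinian abridged life table could be shipped, so
`life_table_synthetic.csv` is a synthetic GBD-style table built from a
Gompertz schedule chosen to give a remaining life expectancy at 40 of about
36 (men) and 40.5 (women) years; it is a labelled, replaceable stand-in,
and the Gompertz other-cause hazard is refitted from whatever table is
supplied.

**Common random numbers.** All uniforms are pre-drawn in a fixed order from
the run seed, so baseline and scenario runs at the same seed are coupled: a
null intervention (all rate ratios 1, zero cost) reproduces the baseline
bit-exactly, and scenario deltas are not masked by Monte-Carlo noise. One
consequence is worth stating precisely: an intervention that only changes a
condition's *incidence* leaves every other condition's incidence stream
untouched, but if the targeted condition has a fatality pathway, averted
deaths extend survival and can spill a few DALYs per 10,000 into other
conditions. Published tables that show exact zeros in such cells are
consistent with this at rounding resolution; the test suite asserts exact
zeros in the construction where the targeted condition has no fatality
pathway, and treats the general case as bounded rather than zero.

## Interventions, reach and costs

The nine modeled WHO interventions ship as a JSON fixture: mechanism
(incidence/mortality rate ratios, or risk-factor shifts such as an SBP
reduction, applied by blending the hazards of a counterfactually shifted
cohort), an eligibility predicate (everyone; women 50–69 for mammography;
diagnosed asthma/COPD for inhaler therapy; incident cases for the cancer
treatments), a reach curve, and a cost basis. The published unit costs are
encoded as printed ($0.20, $4, $0.30, $19, $110, $20 per person-year;
$14,736 and $1,423 per incident case; $24 per asthma/COPD person-year).
Effect rate ratios are literature-style defaults and clearly replaceable;
analyses that must match published effect sizes configure condition deltas
directly from the effect panel fixture instead of relying on them.

**Reach convention.** "Starting from a 64% reach rate with a linear
implementation period over the 10-year horizon" admits two readings: ramp
*up to* 64%, or *start at* 64% and scale up. The package implements
`immediate` (constant), `linear_over_horizon` (`reach x (t+1)/H`) and
`linear_from_start` (`reach + (1-reach)(t+1)/H`). The library default is
`linear_from_start`, the literal reading of "starting from", and the one
whose discounted person-year weight (7.286 of 10 years at 3%) makes the
printed unit costs reproduce the published ICER magnitudes; the other ramps
remain one argument away. Reach enters in expectation by default — an
eligible individual's hazard is multiplied by `1 - r(t)(1 - RR)` — which
makes scenario effects smooth in reach; a per-individual reach draw
(`mode = "rng"` in `apply_intervention()`) is available.

Costs accrue over reached person-years (or reached incident cases) with
annual discounting; per-incident-case costing in the panel-configured
economics spreads the baseline 10-year incidence uniformly over the horizon.
ICERs follow the sign conventions of the field (`dominant` when saving money
while averting DALYs, `dominated` when costing money and averting none) and
are classified against exclusive GDP bands — at or below 1x GDP per capita
($3,664), at or below 3x ($10,992), above — with boundary values assigned
downward. A $34 ICER is therefore reported as `below_1xGDP`, which is a
fortiori below the 3x threshold. The package classifies strictly by the
numeric rule; published prose that lists $14,840 or $17,054 interventions
as below-threshold conflicts with the printed $10,992 bound and is not
reproduced.

## Uncertainty

`run_psa()` propagates parameter uncertainty parametrically: unit costs as
truncated normals (default CV 25%, a standard costing-uncertainty
assumption) and effect sizes either as DALY-delta normals (panel mode, SD
from the effect panel's interval width) or as log-scale rate-ratio draws
with full scenario re-simulation per draw (engine mode, common random
numbers shared across draws). Plain-normal sampling cannot guarantee
admissible draws, hence truncation and the log scale for ratios. The
desk-scale default is 1,000 draws; all summaries report the mean and
2.5/97.5 percentiles of the same draw set. `reach_sweep()` re-runs the
scenario comparison across reach values under a shared seed; DALYs averted
and costs scale linearly in reach within Monte-Carlo tolerance, leaving the
ICER invariant, which the suite checks on an isolated-condition cohort of
20,000.

## Problem sizes and runtime choices

The shipped defaults are chosen so every check runs comfortably on one CPU:
the generator is exercised at the survey size (4,576); calibration and
baseline-reproduction checks use cohorts of 2,000–10,000; the
competing-risk oracle uses 2x10^5 one-year draws; linearity checks use
20,000 individuals; PSA checks use 200–1,000 draws. The full pipeline
(`run_pipeline()`) defaults to the survey size resampled to a 10,000-person
reporting cohort, the scale on which all per-10,000 results are defined.

## Limitations

* The generator's dependence matrix is an informed default, not an
  estimate; joint-structure-sensitive results should be read accordingly.
* Conditions are single states: no severity progression, remission or event
  sequelae; "mortality" is condition-attributed case fatality, not excess
  all-cause mortality.
* Risk-score coefficients are replaceable shapes rescaled by calibration,
  not validated re-implementations of the source cohort models.
* Effect-size defaults for the nine interventions are indicative; published
  per-intervention ICER reproduction relies on the panel-configured route.
* The asthma/COPD treatment ICER is not reconcilable with its prevalence,
  unit cost and horizon by simple arithmetic under any shipped cost basis;
  the cost base is configurable and the default (per diagnosed person-year)
  is documented here.
* The life table is a labelled synthetic stand-in; replace it with a
  published abridged table for substantive work.
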