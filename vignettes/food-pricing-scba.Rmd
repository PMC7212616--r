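---
title: "Methods: social cost-benefit analysis of food pricing policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social cost-benefit analysis of food pricing policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodscba)
```

## The model

The package compares a policy scenario — a 15% or 30% consumer price
increase on all meat, or a 10% price decrease on fruit and vegetables — to a
no-policy reference over 30 annual cycles (base year 2018, endpoint 2048).
The chain is: price change → consumption → (a) chronic-disease burden and
QALYs and (b) environmental burden → monetized societal effects → a
discounted ledger stratified by consumers and government.

### Consumption

Each age-sex cell carries a mean daily intake per food group (red meat,
processed meat, poultry, fruit & vegetables). The reference trajectory
holds cell means constant: intake varies by age and sex but has no
autonomous time trend, which mirrors the absence of conclusive evidence for
one in national consumption series. A price intervention multiplies every
cell of the priced groups by the elasticity response from the first policy
year onwards, with full immediate pass-through (no phase-in is modelled
because none is specified for the policies studied).

Two functional forms connect the price change \(\Delta p\) to quantities:
iso-elastic \(q_1 = q_0 (1+\Delta p)^{\varepsilon}\) (default) and linear
\(q_1 = q_0 (1 + \varepsilon \Delta p)\). The elasticity of demand is a
point estimate with a 95% CI: meat −0.60 (−0.66, −0.54), fruit and
vegetables −0.53 (−0.59, −0.48). **Design note.** Published endpoint
figures for these scenarios (98.2, 90.3 and 261 g/day from baselines of 107
and 250 g/day) sit between the two closed forms and closest to the
iso-elastic one; the residual gap (up to ~1.3%) is consistent with intake
categorization inside the dynamic microsimulation software those figures
come from, an effect we deliberately do not emulate because its
categorization rule is not published. The iso-elastic form is therefore the default and the gap is
a documented property of the package, not a calibration target.

### Health

The health engine is a deterministic multistate ("macro") implementation of
a Markov-type risk-factor/disease model. Cells carry proportions rather
than simulated individuals: this is exactly the expectation of the
corresponding microsimulation under independence, is fully reproducible,
and leaves the Monte-Carlo effort for parameter uncertainty, the dominant
source of uncertainty in this class of model.

* **Exposure.** Within a cell, intake is gamma distributed with the cell
  mean and a common shape parameter (default 4): intakes are non-negative
  and right-skewed, and a two-parameter family is the most structure the
  available summary statistics support. Category proportions are gamma tail
  masses between the cut-points (meat 0–50 / 50–100 / >100 g/day; F&V
  0–150 / 150–300 / >300 g/day). The health-relevant meat exposure is red
  plus processed meat; poultry carries no association (RR ≡ 1) and so
  enters only the market and environment accounts.
* **Incidence scaling.** For each disease the baseline incidence (defined
  as observed under the reference category distribution \(p\)) is scaled by
  \(\sum_c p'_c RR_c / \sum_c p_c RR_c\) under the scenario distribution
  \(p'\) — a potential-impact-fraction argument. Relative risks are
  synthetic placeholders (gradients 1.0–1.4 across categories) because the
  underlying systematic-review values are not published; they are
  configuration, not constants, and the default pattern gives meat its
  strongest gradient for type-2 diabetes and none for coronary heart
  disease, and fruit/vegetables their strongest protective gradient for
  stroke.
* **Dynamics.** Per 1-year cycle: susceptibles acquire each disease with
  probability \(1-\exp(-\text{rate})\) (the standard rate-to-probability
  conversion; the source analysis is silent on this point); prevalent cases
  die at background plus disease-specific excess mortality, treated as
  additive on the rate scale with diseases independent; survivors age one
  year; the age-100 bucket is closed and accumulates its survivors; newborns
  enter at age 0 disease-free. Mortality selection is applied to prevalence
  (cases die faster, so surviving prevalence falls), and population balance
  is exact each cycle: alive(t+1) = alive(t) − deaths + newborns.
* **Utility.** Cell utility is \(1-\sum_d \pi_d w_d\) (prevalence times
  disability weight), floored at 0 — additive comorbidity, the simplest
  rule; a multiplicative option was considered and rejected as spurious
  precision given the synthetic weights. Yearly QALYs are population times
  utility, so the QALY stream counts both morbidity (utility) and mortality
  (population) effects; the ledger uses this total.
* **Uncertainty.** Each Monte-Carlo iteration draws every relative risk
  from a normal distribution on the RR scale (mean = point estimate,
  sd = CI width / 3.92, truncated at 10⁻⁶) and re-runs the scenario; the
  reference run is RR-invariant because its scaling factor is identically
  1. Intervals are 2.5th/97.5th percentiles of 100 iterations —
  percentiles rather than min–max, since a 95% interval over simulation
  draws conventionally means the central 95% of their distribution.
  Zero-width CIs are legal and simply reproduce the point run.

A structural property worth noting: because averted disease lowers
mortality, the surviving population grows, and a disease with RR ≡ 1 can
*gain* absolute cases under a beneficial policy. The engine reproduces this
compensation (coronary heart disease under the meat tax with the default
risk pattern), and the test suite asserts it.

### Environment

National kg per food group times a per-kg footprint gives five indicators
(GHG kg CO₂-eq, acidification kg SO₂-eq, freshwater eutrophication kg P-eq,
saltwater eutrophication kg N-eq, land use m²a). Production efficiency
improves linearly in percentage points of the base-year intensity —
an observed 20% decline over 16 years annualizes to 1.25 %/yr on exactly
this arithmetic, which is why the linear (not compounded) reading is used —
applied uniformly to all indicators and groups. The factor stays positive
over 30 years at both the default and the high (1.75 %/yr) gain. Efficiency
cancels in scenario-vs-reference ratios, so relative impact changes equal
relative consumption changes and are identical across indicators; the per-kg
footprints are synthetic but calibrated to the order of magnitude of Dutch
LCA totals, and satisfy meat > fruit/vegetables in every indicator — the
structural assumption behind all sign conclusions.

### Monetization and assembly

* QALYs at €50,000 (variant €100,000). Under the perfect-information
  variant consumers are assumed to already internalize health in purchase
  decisions, so the QALY row is dropped entirely.
* Environmental unit costs: €0.057/kg CO₂-eq, €5.40/kg SO₂-eq, €3.11/kg
  P-eq, €1.90/kg N-eq, €0.0261/m²a; high/low variants scale these by
  configurable factors (default ×1.5 / ×0.5) because the exact variant
  price sets are not published.
* Healthcare savings: averted prevalent case-years times per-disease
  cost-of-illness rates (synthetic configuration).
* Productivity (working ages 15–75): averted working-age case-years times
  absenteeism+presenteeism costs plus a participation fiscal effect (income
  tax and welfare payments only, to avoid double counting); the friction
  method keeps a configurable fraction (default 0.2) of the participation
  stream. The consumer/government split of productivity is a configuration
  parameter (default 15% to consumers) since the published stratification
  shows entries in both columns without stating the rule.
* Policy revenue: tax income on scenario consumption minus VAT (6%) lost on
  forgone consumption, or VAT gained minus subsidy outlay; prices follow a
  CPI trend (default 1.2 %/yr, a typical food-CPI magnitude, as the source
  series is not printed).
* Consumer surplus: the rule of half. Two forms are implemented — the
  triangle ½(p₀−p₁)(q₀−q₁) exactly as sometimes printed, and the standard
  trapezoid ½(p₀−p₁)(q₀+q₁). The default is the trapezoid: only it produces
  surplus magnitudes on the scale of a national 30-year ledger
  (~€21,000M for a 15% meat tax), so the printed triangle appears to be a
  typographical reduction of the standard rule. Both remain available and
  the discrepancy is documented rather than silently resolved.
* Implementation cost: a single €20M government outflow in the first policy
  year.
* Discounting at 3 %/yr (variants 1.5% and 4%) to 2018 euros; ledger values
  are reported in million euros, accumulated in full precision and rounded
  only for printing. Monte-Carlo bounds propagate only through the
  RR-dependent rows (healthcare, health outcomes, productivity) and the
  grand totals; environment, revenue, surplus and policy-cost rows are
  deterministic given the consumption path.

Stakeholder attribution: health outcomes, the consumer productivity share
and consumer surplus belong to consumers; healthcare savings, the
government productivity share, environment, policy revenue and policy costs
to government. This attribution reproduces the published stratified totals
from their own row entries, which is how it was chosen.

## The synthetic-data generator

The generator emulates the statistical structure of the unavailable inputs:

* **Demography.** A Gompertz–Makeham life table by sex and the stationary
  pyramid it implies, scaled to 16,979,107 persons (the population implied
  by the printed national totals: 665,581,000 kg / 39.2 kg per person);
  newborn inflow equals the stationary age-0 count, so the reference
  population is constant by construction.
* **Diet.** Smooth age profiles (meat rising through childhood, flat in
  adulthood, tapering after 70; male intake 25% above female) with seeded
  log-normal cell noise (sd 0.05), renormalized so the population-weighted
  means hit the targets exactly: total meat 107 g/day (split 42/33/25%
  red/processed/poultry) and fruit & vegetables 250 g/day.
* **Epidemiology.** Exponential-in-age incidence with plausible caps,
  steady-state-style prevalence, and per-disease excess mortality and
  disability weights of textbook magnitude. These are placeholders: the
  original disability and excess-mortality weights were collected within a
  modelling consortium and are not public.

What the generator does **not** emulate: day-to-day intake variance beyond
the gamma model, intake trends, correlation between diet and disease risk at
the individual level, migration, or socio-economic stratification. Passing
tests therefore demonstrate the correctness and internal consistency of the
pipeline under realistic structure — not the euro totals of any real
population. The consumption and environment endpoints are the exception:
they follow from printed inputs and are reproduced quantitatively.

## Numerical choices and degenerate inputs

* Rates are converted to probabilities per cycle as 1 − exp(−rate), which
  keeps probabilities in [0,1] for any non-negative rate.
* `categorize_intake` treats zero dispersion (infinite gamma shape) as a
  point mass and a zero mean as all mass in the lowest category; category
  boundaries must be strictly increasing (a named validation error
  otherwise).
* The net-flow transition estimator between adjacent categories is the
  cumulative-difference solution — the unique flow vector with no
  simultaneous two-way exchange; it conserves mass exactly. It replaces the
  published penalized-spline transition-rate estimator, which is out of
  scope here.
* The efficiency factor errors out rather than going non-positive, so a
  configuration whose horizon would exhaust the intensity is rejected.
* All validation failures raise conditions of class
  `foodscba_validation_error`.
* Reproducibility: one integer seed drives both the generator noise and the
  Monte-Carlo draws; identical seeds give bit-identical bundles, health
  states and ledgers.

## Problem sizes

The shipped configuration simulates 101 ages × 2 sexes × 5 diseases over 30
one-year cycles, with 100 Monte-Carlo iterations per policy scenario —
small enough to run an entire scenario in seconds on one core, which is the
size chosen for the examples, the test suite (which scales the grids down
further for hand-checkable oracles) and the acceptance script.

## Known limitations

* No cross-price substitution: a cheaper or dearer food group does not move
  the others, because usable cross-elasticities do not exist for this
  setting; substitution toward (or away from) other foods would change both
  the health and the environmental balance.
* One risk factor changes per scenario; a combined tax-plus-subsidy
  scenario is therefore out of scope.
* Euro totals depend on synthetic prices, cost-of-illness and RR inputs and
  are illustrative; sign patterns, accounting identities and the
  consumption/environment endpoints are the quantitatively meaningful
  outputs.
* The macro health engine tracks marginal prevalences under independence;
  individual risk-factor histories and disease clustering are not modelled.
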