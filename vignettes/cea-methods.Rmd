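---
title: "Methods: decision-analytic cost-effectiveness of pulse-oximetry-augmented IMCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-analytic cost-effectiveness of pulse-oximetry-augmented IMCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxicea)
```

## The question and the model

Two strategies for diagnosing severe pneumonia in children aged 2–59
months at first-level health centres are compared: the IMCI clinical
algorithm alone (control) and IMCI combined with fingertip pulse
oximetry, where oxygen saturation below 90% also qualifies a child as
severe (intervention). The evaluation is trial-based: effect and cost
inputs come from a two-arm cluster-randomized trial (24 health-centre
clusters, about 1,800 children over an 8-month window), and the health
outcome is an intermediate one — a diagnosed severe pneumonia case —
because no reference-standard diagnosis exists in these settings and
the follow-up was too short for mortality endpoints. Costs are 2018
USD from both the provider and the patient perspective, undiscounted
(the horizon is under a year).

Each strategy is a small probability tree over mutually exclusive
pathways. A child is diagnosed severe with the arm's probability
$p_s$; the severe-diagnosis branch then splits into true positives
(arm sensitivity) and false positives, and the non-severe branch into
true negatives (arm specificity) and false negatives. Severe-diagnosis
leaves carry the arm's average severe-case cost, the other leaves its
non-severe average cost. Expected cost and effect per child are the
probability-weighted payoff sums (rollback), so for the base case

$$E[C_s] = p_s \bar{C}^{sev}_s + (1-p_s)\bar{C}^{non}_s,
\qquad E[E_s] = p_s \cdot se_s,$$

and the incremental cost-effectiveness ratio is
$\mathrm{ICER} = \Delta C / \Delta E$ in USD per extra diagnosed
severe case.

**Effect definitions.** The package supports two payoff conventions,
selected by `effect_definition`:

* `"true_positive"` (default): only leaves that are both diagnosed
  severe and truly severe count, $E[E_s] = p_s \cdot se_s$. This is
  the coherent role for the sensitivity inputs in a base-case rollup,
  and it puts the base ICER (38.31 USD) right next to the
  probabilistic rank-swap threshold (39 USD), which is how an
  acceptability analysis and its base case should relate.
* `"any_severe_diagnosis"`: every severe-diagnosis leaf counts,
  $E[E_s] = p_s$, ICER 36.27 USD. Useful when the outcome is read
  literally as "cases labelled severe".

With perfect sensitivity the two definitions coincide (a tested
invariant). Both are kept because the counting convention behind the
published headline figure for this kind of analysis is typically not
machine-readable; the package documents its rollup rather than forcing
agreement with any single printed number.

## Parameters

The packaged table (`default_parameters()`) has ten rows; every row
carries a base value, interval bounds (min/max), an SD, and a
distribution family.

| parameter | base | units | role |
|---|---|---|---|
| `cost_severe_intervention` | 25.74 | USD/case | gamma |
| `cost_nonsevere_intervention` | 3.58 | USD/case | gamma |
| `cost_severe_control` | 17.98 | USD/case | gamma |
| `cost_nonsevere_control` | 2.14 | USD/case | gamma |
| `p_severe_intervention` | 0.16 | proportion | beta |
| `p_severe_control` | 0.04 | proportion | beta |
| `sens_intervention` | 0.85 | probability | beta |
| `spec_intervention` | 0.87 | probability | beta |
| `sens_control` | 0.56 | probability | beta |
| `spec_control` | 0.87 | probability | beta |

Conventions adopted where the source material names families but not
mechanics:

* **Method of moments** maps (base, SD) to distribution parameters in
  closed form — gamma `shape = (mean/sd)^2`, `scale = sd^2/mean`; beta
  $\alpha = \mu\nu$, $\beta=(1-\mu)\nu$ with
  $\nu = \mu(1-\mu)/\sigma^2 - 1$. This is the standard
  parameterization for health-economic PSA; the fit round-trips the
  input mean and SD to 1e-9 relative error (tested).
* **SD drives the PSA; min/max drive the tornado.** The interval
  bounds are used only for one-way sensitivity analysis, never as
  distribution quantiles.
* **Shared specificity draw.** The combined strategy's specificity is
  an assumption of equality with IMCI alone, not an independent
  estimate, so by default the two specificity rows share one draw per
  PSA iteration (`psa_config(shared_draw_groups = ...)`; pass
  `list()` for independence). Group members are validated to have
  identical distribution parameters.
* Probability rows may declare `distribution = "fixed"` (with
  `sd = 0`), which keeps degenerate configurations — useful for
  deterministic checks — inside the validated type.

## Costing

Capital items (the oximeter, 149.81 USD, expected life 2 years) are
annuitized at 7% interest and pro-rated over the 8-month costing
window: annual equivalent 82.86 USD, so one device contributes about
55 USD to the window. The annuity factor is computed as
`-expm1(-n*log1p(r))/r`, which is the closed form without the
cancellation that breaks the naive expression for tiny `r`; the
`r -> 0` limit `price/n` is exact to machine precision (tested at
`r = 1e-12`).

Variable costs multiply recorded quantities by unit costs: oxygen per
m³, hospital stay per day, transport per km, drugs/IV fluids/cannulae
per unit, one consultation per child, personnel per consultation at
arm-specific rates. Fixed provider costs (device, batteries, training,
personnel time) are attributed once per arm to the severe-case ledger
— the class whose diagnosis they exist to improve — and only when the
arm has at least one severe case to carry them; an arm with no severe
diagnoses reports an empty severe ledger and an explicit "no cases"
marker instead of a division by zero.

The per-consultation personnel rates (0.59/0.34 USD) are taken as
given unit costs. The allocation from annual salary (1,474 USD) and
duty fees (2,580 USD) requires a time fraction that is
facility-specific; `personnel_unit_cost()` exposes that computation
with the fraction as an explicit argument rather than hard-coding one.

Display rounding is confined to reports: USD at two decimals, shares
at integer percent. Because each share is rounded independently, a
ledger with $k$ items can have shares summing anywhere in
$100 \pm k/2$; the packaged nine-item ledger sums to 102, and the
tests assert the exact $k/2$ bound rather than a cosmetic one. The
packaged control-arm itemized entries sum to 612 USD while the class
total is elsewhere printed as 611.30 (hidden decimals); `itemize()`
reports the recomputed sum and leaves the discrepancy visible.

## Sensitivity analyses

**Tornado.** Each parameter in turn is set to its min and max with all
others at base, and the ICER is recomputed. Ends where one strategy
dominates are reported as statuses (`dominant`/`dominated`), not
coerced to numbers: ICERs are not comparable across dominance regimes.
Entries sort by spread descending, ties broken alphabetically, and
undefined-spread entries sort last — making the output a pure function
of the inputs (bit-identical across runs and input permutations,
tested).

**PSA.** All parameters are sampled jointly (10,000 iterations by
default) from their fitted distributions with a single seeded
generator, consuming parameters in table order then iterations, so the
entire output is bit-reproducible for a given seed. Each draw is
rolled back through the tree vectorized. Strategy preference uses net
monetary benefit, $\mathrm{NMB}_s = \lambda E_s - C_s$: ranking by
per-draw ICER is ill-defined under sign changes, while for two
strategies NMB is provably equivalent to the rule
$\Delta C/\Delta E < \lambda$ whenever $\Delta E > 0$ (verified
draw-by-draw in the tests). The CEAC reports, at each $\lambda$ on a
0–100 USD grid (step 1, covering all thresholds of interest), the
fraction of draws in which each strategy has the strictly highest NMB,
ties split equally; the crossover is the smallest grid $\lambda$ at
which the intervention's probability reaches the comparator's, with a
linear interpolation of the crossing reported alongside. Draws with
$\Delta E = 0$ (a measure-zero event under continuous sampling) are
excluded from ratio summaries and counted.

## The synthetic trial generator

`generate_trial()` emulates the structure the costing consumes: 24
clusters randomized 12:12, negative-binomial cluster sizes (mean
1804/24 ≈ 75, dispersion 8 — overdispersion is realistic for
facility caseloads), Bernoulli severe diagnosis at 148/928 ≈ 0.1595
(intervention) and 34/876 ≈ 0.0388 (control), and per-child item
quantities drawn from right-skewed non-negative distributions: gamma
(shape 2) for continuous quantities (km travelled, oxygen m³), Poisson
for counts (hospital days, doses, cannulae), one consultation per
child. Severe-only items (oxygen, hospital days) are identically zero
for non-severe children.

Quantity means are calibrated so the expected per-case itemized costs
reproduce the study-level class averages: severe-case means are the
itemized severe ledgers divided by case counts and unit costs (e.g.
transport 559/148/0.03 ≈ 126 km per severe intervention case);
non-severe itemized costs are not published, so their mix is an
assumption — one consultation, one drug dose, and the remainder as
transport — calibrated to the class averages 3.58/2.14 USD. A
`deterministic_quantities` switch replaces draws by point masses, and
an optional lognormal cluster random effect (`cluster_sd`) induces
within-cluster cost correlation for robustness experiments; it is off
by default because the analysis consumes arm-level aggregates.

What passing tests show — and do not show. The generator preserves
means, class labels and cluster structure, which is all the costing
estimators consume; parameter recovery within 3 standard errors across
100 seeds (a tested property) therefore validates the estimator
plumbing, not the realism of cost distributions. Real trial data have
features the generator omits: correlated item quantities within a
child, informative cluster-level variation in severity, seasonal
caseloads, and measurement error in caregiver-reported expenses.

## Numerical and testing choices

* Chance-node probabilities must lie in [0, 1] and sum to 1 within
  1e-9 at every node for the supplied assignment; violations raise
  errors naming the node. Branch probability expressions are
  restricted to a parameter or its complement, which makes the sum
  constraint hold identically for complementary pairs.
* Rollback is checked against an independent path-enumeration oracle
  on randomly generated trees up to depth 6 (agreement to 1e-12).
* The beta fit rejects $\sigma^2 \ge \mu(1-\mu)$, including the
  $\alpha=\beta\to 0$ boundary, via a `nu > 1e-9` tolerance.
* Problem sizes in the test suite — 10,000-iteration PSAs, 20-seed
  crossover stability, 100-seed recovery, $10^6$-draw moment checks —
  were chosen so each property is tested at the scale the analysis
  itself uses while the whole suite stays quick to run.
* All entry points are pure functions of (inputs, seed): repeated runs
  write byte-identical CSV/JSON artefacts, and run logs record the
  seed, the parameter-table checksum and the package version.

## Limitations

The outcome is an intermediate one; no link to deaths averted or DALYs
is modelled, and averted downstream costs from better diagnosis are
not estimated. False positives are costed like true positives (they do
occupy the same referral pathway) but carry no harm term. The
two-strategy pairwise comparison does not generalize to a multi-way
frontier, and no Markov extension, half-cycle correction, correlation
structure beyond the shared specificity draw, or value-of-information
analysis is provided.
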