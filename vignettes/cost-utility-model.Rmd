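---
title: "A decision-tree + Markov cost-utility model for laboratory screening in acquired comitant esotropia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree + Markov cost-utility model for laboratory screening in acquired comitant esotropia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acescreen)
```

## The question the model answers

Acquired comitant esotropia (ACE) is mostly idiopathic, but in a small
fraction of patients it is the presenting sign of ocular myasthenia
gravis (OMG) or of thyroid dysfunction, both treatable. Baseline
laboratory screening — an acetylcholine receptor antibody (AChR-Ab) assay
plus thyroid function tests (TFT) — finds those patients early; at a 2.7%
OMG prevalence and a 0.9% thyroid-dysfunction prevalence, it also tests
very many patients who have neither condition. The model weighs the
quality-of-life gain of early diagnosis against the cost of universal
testing, from a healthcare-sector perspective in 2024 Thai Baht, and asks
whether the incremental cost per quality-adjusted life year (QALY) clears
Thailand's willingness-to-pay (WTP) band of ฿160,000–200,000 per QALY.

## Decision tree

For each test, prevalence $\pi$ and accuracy $(Se, Sp)$ partition the
cohort into four branches:

$$P(TP) = \pi\,Se, \quad P(FN) = \pi(1-Se), \quad
  P(FP) = (1-\pi)(1-Sp), \quad P(TN) = (1-\pi)\,Sp.$$

Branches map to initial Markov states: true positives start in the
early-diagnosed (treated) state; false negatives in the delayed,
undiagnosed state; true negatives in idiopathic ACE; false positives
return to idiopathic ACE after a one-cycle confirmatory workup (chest CT
+ two extra visits, ฿9,700) with no lasting disutility. In the
no-screening arm every diseased patient starts undiagnosed; detection
then happens only through the Markov model's symptom-triggered detection
rate. The two tests sit on parallel branches and the two diseases are
treated as mutually exclusive: their joint mass at the observed
prevalences (≈0.02%) is far below the model's resolution.

The TFT is modelled as one composite TSH-first reflex test with the
stated composite accuracy (Se 0.90, Sp 0.92), while the universal arm is
charged for all three assays (TSH ฿170, FT3 ฿170, FT4 ฿150) — the panel
is priced per component, but its diagnostic behaviour is published only
as a composite. MRI of the brain and orbit (฿16,000) is routine for every
ACE patient regardless of strategy, so it is charged in all arms and
cancels exactly from every incremental comparison (the package keeps it
in the cost ledger so absolute totals stay interpretable).

The targeted strategy is a proportional application of universal
screening to 30% of the cohort, with the remaining 70% following the
no-screening pathway. No risk enrichment is modelled — the targeted
subgroup keeps the cohort prevalence — so its costs and QALYs are exactly
the 0.30-convex combination of the two pure strategies, a property the
test suite verifies at $f \in \{0, 0.3, 1\}$. A corollary worth knowing:
with identical prevalence in the subgroup, the targeted ICER equals the
universal ICER; targeted screening spends and gains proportionally less.

## Markov model

Seven states: idiopathic ACE, early-diagnosed OMG, delayed/undiagnosed
OMG, generalized MG, treated hypothyroidism, undetected hypothyroidism,
and death (absorbing, background mortality only). Annual cycles, 10-year
horizon. Edges: OMG states may progress to generalized MG or die;
delayed/undetected states are found at the symptom-triggered detection
rate and move to their diagnosed counterpart; idiopathic patients may
newly develop either disease (off by default) or die; everyone faces
background mortality.

The annual transition probabilities behind the published cohort totals
are not in the public record. The package ships defaults — background
mortality 0.005/yr (a flat placeholder in the 30-year-old cohort's
range), progression of untreated or treated OMG to generalized MG
0.05/yr, incident disease 0/yr, symptom-triggered detection 0.25/yr
(median time to detection ≈ 2.4 years, consistent with "detected during
routine follow-up") — every one labelled `"default"` provenance,
reported by `provenance_report()`, overridable from the parameter file,
and exposed to sensitivity analysis. Absolute cohort totals therefore
constitute the package's own base case rather than a reproduction of any
published table; incremental *structure* (which parameters drive results,
which quadrant the PSA occupies) is much less sensitive to these rates
than the absolute ICER is.

### Utilities

| state | utility | notes |
|---|---|---|
| idiopathic ACE / true negative | 1.000 | full health |
| early-diagnosed OMG | 0.872 | published weight |
| delayed/undiagnosed OMG | 0.739 | published weight |
| generalized MG | 0.739 | unpublished; defaults to the delayed value |
| hypothyroidism (treated or undetected) | 0.94 | the same weight is published for subclinical, treated and delayed disease |
| death | 0 | by definition |

Two parametrization choices matter for sensitivity analysis. First, the
OMG pair is carried as (early utility, delay decrement = 0.133): the
decrement is the literature-anchored harm of late diagnosis, so the
one-way analysis varies the *decrement* as its own bar, and varies the
early utility as a joint shift of both OMG states that preserves the
decrement. Varying the early utility alone would mechanically produce a
mirror-image bar of the decrement (detection moves person-years between
the two states almost one-for-one), double-counting a single source of
uncertainty. Second, both thyroid states share the single published 0.94
weight, so thyroid screening moves patients between equal-utility states
and contributes cost but almost no QALYs — the model's counterpart of the
observation that TFT screening adds minimal benefit at 0.9% prevalence.
The 0.965 "missed condition managed as idiopathic" weight is retained in
the utility table for alternative state mappings but is not attached to
any state by default.

### Accounting modes

Published cohort QALY totals appear on two scales: a base case near 1
QALY per patient over 10 years, and a scenario near 8.5 per patient. No
single accumulation rule yields both, so the engine implements two modes
and stamps every result with the one used:

* **accumulated** (default) — standard state-utility × person-time:
  $\mathrm{QALY} = \sum_{k=0}^{H-1} (1+r)^{-(k+1)}
  \tfrac12\,u^\top(x_k + x_{k+1})$, where $x_k$ is the occupancy vector.
  A full-health immortal cohort of 110 accrues
  $110 \times \frac{1 - 1.03^{-10}}{0.03} = 938.32$ QALYs — the ~8.5 per
  patient scale.
* **endpoint** — the accumulated total divided by the full-health annuity
  $\sum_k (1+r)^{-k}$: a discount-weighted average utility scaled to the
  cohort, bounded by the cohort size — the ~1 per patient scale.

The two differ by a fixed factor, so ICER *orderings* agree; absolute
ICERs do not, and sensitivity analyses default to accumulated mode (the
conventional accounting, and the one on which cost and utility bars are
commensurable).

### Numerical conventions

Half-cycle correction is trapezoidal: person-time in cycle $k$ is the
mean of the occupancies at its two ends. Each cycle's costs and QALYs are
discounted once, with the end-of-cycle factor $(1+r)^{-(k+1)}$; this
makes the full-health total equal the textbook annuity exactly, which
the tests pin down ($r=0$ gives cohort × horizon; $r=0.03$ gives
cohort × 8.530203). One-time decision-tree costs land undiscounted at
year 0. Follow-up visits (two per year at ฿750) are charged to alive
patients for the first three years only — six visits per patient. All
internal arithmetic is per-patient in exact doubles; cohort scaling
(×110) and rounding to whole THB happen at report time, and the tests
verify the ICER is invariant to the cohort scale.

## Sensitivity analyses

**One-way (tornado).** Each parameter moves ±20% from base
(`settings$dsa_variation`); the outcome is the change in net monetary
benefit at λ = ฿160,000 for universal vs. no screening. Probabilities and
utilities pushed past 1 are clipped with a warning (a 1.0 utility cannot
rise). The default parameter list contains the prevalences, the unit
costs (assay, TFT panel, chest CT, MRI, visit) and the utility
parameters; test sensitivity and specificity are registered but excluded
from the default list, because ±20% around Sp = 0.98 reaches 0.784 — a
value no assay evaluation reports — and the resulting false-positive
surge would dominate the diagram with an artefact of the variation rule.
Accuracy uncertainty is instead propagated through the PSA, where beta
distributions keep draws in plausible ranges. Callers can still pass
`vary = c(..., "spec_achr_ab")` explicitly.

**Probabilistic.** Every stochastic parameter is drawn independently:
beta for probabilities and utilities, parameterized $\alpha = p\,n$,
$\beta = (1-p)\,n$ with $n$ = the evidence cohort size where counts
exist (110 for the prevalences) and $n = 100$ otherwise; gamma for
costs, $k = \mu^2/\sigma^2$, $\theta = \sigma^2/\mu$ with
$\sigma = 0.2\mu$ (a 20% coefficient of variation — the natural reading
of "variance ±20% of the mean", whose literal reading has wrong units).
The OMG utilities are drawn as (early, decrement) for the same reason as
in the DSA; the idiopathic utility of 1.0 is a degenerate boundary and
stays fixed. One root seed drives a single RNG stream with a fixed,
documented sampling order (one column of draws per parameter), which
gives bit-identical reproducibility without per-parameter substream
bookkeeping; the seed is recorded in the result object and in the run
manifest. Default draw count 10,000.

**Two-way threshold.** The deterministic ICER is recomputed on a grid of
AChR-Ab prices (฿0–3,000 by 100) × MG prevalences (0.5–10% by 0.25%),
with the cost-effective region (ICER ≤ λ, or dominant) and the crossing
contour flagged. The ICER is nonincreasing in prevalence and
nondecreasing in price — both property-tested — so the frontier is
monotone.

## Synthetic cohorts

`generate_cohort()` emulates the marginal structure of the 110-patient
series: sex 50/50; ACE type 7.2/46.4/46.4%; age truncated-normal
(30.3, 20.5) on [3, 84] (the truncation pulls the mean up ~1 year —
tests compare against the closed-form truncated mean, not 30.3);
mutually exclusive disease statuses at the model prevalences; test
results drawn through Se/Sp conditional on status. Refraction and onset
duration are log-skewed cosmetic covariates matched to the reported
location and range; the economic model never reads them. What the
generator does **not** emulate: correlations between age, type and
disease status, the four real positive patients' narratives, referral
patterns, or any time axis — so passing tests show the pipeline is
arithmetically faithful to its declared margins, not that the model
generalizes to a differently structured clinic population.

## Problem sizes and runtimes

The test suite runs ~1,700 assertions in about 20 s on one core:
property tests use 50–200 random replicates, the PSA moment checks use
10,000 draws (a few seconds — each draw is a 7×7 matrix projection over
10 cycles), distributional fidelity of the cohort generator is checked
at n = 100,000, and the path-enumeration Markov oracle is applied to
3-state, 3-cycle toys where exhaustive enumeration is feasible.

## Known limitations

* Absolute costs and QALYs depend on the default-provenance transition
  rates; only their structure (orderings, quadrants, tornado ranking) is
  robust to them. Anyone with better rate estimates should override the
  `transitions` block.
* No age-specific life tables; background mortality is flat.
* No correlation structure in the PSA; no value-of-information analysis.
* Treatment costs (pyridostigmine, levothyroxine) default to ฿0 so that
  the base case is reproducible from published unit costs alone; users
  with local prices should set `costs.annual_treatment_*`.
* The targeted strategy is a testing-volume reduction, not a validated
  risk-stratification rule; with subgroup enrichment it would need a
  separate prevalence parameter, which the schema does not yet model.
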