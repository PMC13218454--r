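# acescreen

Cost–utility analysis of routine laboratory screening in acquired comitant
esotropia (ACE).

ACE — sudden-onset inward eye deviation that is equal in all gaze
directions — is usually idiopathic, but can be the first and only sign of
ocular myasthenia gravis (OMG) or thyroid dysfunction. Should every ACE
patient therefore get a baseline acetylcholine receptor antibody (AChR-Ab)
assay and thyroid function tests (TFT), or only those whose symptoms later
raise suspicion? `acescreen` implements the decision-analytic model that
answers this question for a resource-constrained health system (costs in
2024 Thai Baht, Thai willingness-to-pay thresholds), for health-economics
analysts and clinical researchers who want to rerun, perturb or extend the
analysis.

## The model

Three strategies are compared on a cohort of 110 patients:

* **none** — no routine screening; disease is detected only when symptoms
  emerge during follow-up;
* **universal** — every patient is tested at baseline with AChR-Ab
  (Se 0.75, Sp 0.98) and a TSH-first TFT panel (Se 0.90, Sp 0.92);
* **targeted** — the universal pathway applied to the 30% of patients with
  higher pre-test probability, the rest managed as in **none**.

A decision tree converts prevalence π and test accuracy into branch mass
(TP = π·Se, FN = π·(1−Se), FP = (1−π)·(1−Sp), TN = (1−π)·Sp) and assigns
each branch an initial health state and one-time cost. A Markov cohort
model with annual cycles then projects 10 years of state occupancy across
seven states (idiopathic ACE, early-diagnosed OMG, delayed/undiagnosed
OMG, generalized MG, treated and undetected hypothyroidism, death), with
half-cycle correction and 3% annual discounting of costs and QALYs.
Strategies are compared by the incremental cost-effectiveness ratio

    ICER = (Cost_screen − Cost_no-screen) / (QALY_screen − QALY_no-screen)

and by net monetary benefit NMB(λ) = λ·ΔQALY − ΔCost against the Thai
willingness-to-pay band λ = ฿160,000–200,000 per QALY.

Uncertainty is handled three ways: one-way deterministic sensitivity
analysis (±20%, tornado ordering), probabilistic sensitivity analysis
(10,000 Monte-Carlo draws; beta distributions with α = p·n, β = (1−p)·n
for probabilities and utilities, gamma distributions with k = μ²/σ²,
θ = σ²/μ for costs) with cost-effectiveness plane, ICER histogram and
acceptability curve, and a two-way AChR-Ab-price × MG-prevalence
threshold grid.

The annual Markov transition rates behind the published cohort totals are
not in the public record; the package ships auditable defaults (flagged
`"default"` provenance, all overridable and all eligible for sensitivity
analysis), so its absolute totals are its own base case, not a
reproduction of the published table. See the methods vignette
(`vignettes/cost-utility-model.Rmd`) for every default and its rationale.

## Worked example

```r
library(acescreen)
p <- default_parameters()         # base case; or load_parameters("file.yaml")
fit <- ace_cua(p)
summary(fit)
```

```
Strategies vs. 'none' at WTP 160,000-200,000 THB/QALY:
Cost-utility comparison (accumulated mode, 10-year horizon, 3% discount)
  strategy    qalys      cost icer_vs_reference
      none 910.9902 2,223,276         Reference
  targeted 911.2107 2,333,753           501,148
 universal 911.7251 2,591,532           501,148
  targeted: not_cost_effective
  universal: not_cost_effective
```

Reading: over 10 discounted years the 110-patient cohort accrues ~911
QALYs without screening; universal screening adds 0.73 QALYs (earlier OMG
treatment for the 2.7% who have it) at an extra cost of ฿368,256, an ICER
of ฿501,148 per QALY — far above the Thai threshold, so screening is not
cost-effective under the package defaults. Targeted screening is the
exact 30% blend of the two pure strategies, so it shares the same ICER
while spending less in absolute terms.

Incremental economics can also be applied directly to published cohort
totals:

```r
no_screen <- strategy_result("none", 1653500, 105.45, mode = "endpoint")
targeted  <- strategy_result("targeted", 1986200, 106.70, mode = "endpoint")
icer(no_screen, targeted, wtp = c(160000, 200000))
```

```
targeted vs none (endpoint mode):
  delta cost 332,700 THB, delta QALYs 1.2500
  ICER 266,160 THB/QALY (tradeoff_NE)
  NMB at WTP 160000: -132,700 THB
  NMB at WTP 200000: -82,700 THB
```

Other entry points: `one_way_dsa()` (tornado), `run_psa()` + `ceac()`
(probabilistic analysis), `two_way_threshold()` (price–prevalence grid),
`generate_cohort()` / `summarize_cohort()` (synthetic patient-level data),
and `run_full_suite()` to write the whole report bundle — tables, figures
and a reproducibility manifest — to a directory.

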