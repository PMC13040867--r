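---
title: "Modelling the cost-effectiveness of perioperative immunotherapy in resectable melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of perioperative immunotherapy in resectable melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periomel)
```

## The decision problem

Patients with resectable stage III--IVC melanoma are conventionally treated
with surgery followed by adjuvant immunotherapy. Randomised trials have
shown that giving part of the immunotherapy *before* surgery (perioperative
strategies) substantially improves event-free survival (EFS). `periomel`
implements two Markov cohort models that translate that EFS benefit into
lifetime costs and quality-adjusted life-years (QALYs) from the US payer
perspective:

* **Model 1** — perioperative nivolumab 240 mg + ipilimumab 80 mg every
  3 weeks for 2 cycles, surgery at week 6, then response-adapted adjuvant
  therapy (none after a pathological complete response; dabrafenib +
  trametinib for 46 weeks in BRAF V600E/V600K-mutant disease, nivolumab
  480 mg every 4 weeks for 11 cycles in wild-type disease), versus surgery
  followed by adjuvant nivolumab 480 mg every 4 weeks for 12 cycles
  (stage III).
* **Model 2** — perioperative pembrolizumab 200 mg every 3 weeks
  (3 neoadjuvant cycles, surgery at week 9, 15 adjuvant cycles) versus
  surgery followed by 18 adjuvant cycles (stage IIIB--IVC).

Each arm is simulated as a cohort moving weekly through six health states:
event-free, locoregional recurrence, locoregional remission, metastatic
progression-free, metastatic disease progression, and death. The horizon is
40 years (2080 weekly cycles) from a start age of 62 years (the midpoint of
the trials' median ages); costs and QALYs are discounted at 3% per year,
compounded weekly as $(1.03)^{-t/52}$.

## Event-free survival and the cure plateau

EFS for each arm is a Gompertz curve
$S(t) = \exp\{-(b/a)(e^{at} - 1)\}$ with weekly shape $a$ and rate $b$.
All four fitted shapes are negative, so each hazard decays geometrically
and the curve plateaus at the cure fraction $e^{b/a}$ — between 40% and
72% of patients never experience an EFS event. In model 1 the perioperative
arm's EFS is the adjuvant arm's Gompertz curve under a proportional hazard
(rate multiplied by the subgroup hazard ratio, which leaves
$S_{\text{new}} = S_{\text{old}}^{HR}$ exactly); model 2 uses each arm's own
fit. The per-cycle event probability is computed from the cumulative-hazard
increment, $q_k = 1 - \exp\{-(b/a)e^{ak}(e^{a}-1)\}$, a cancellation-free
form that stays strictly decreasing across the whole horizon.

### Splitting events between recurrence and metastasis

The published arm-specific weekly probabilities of moving from event-free
to metastatic progression-free are, in every arm, 49--51% of that arm's
Gompertz rate parameter — i.e. they describe the *metastatic share of EFS
events at time zero*, not a hazard that persists after the EFS hazard has
died out. The engine therefore splits each cycle's EFS events (beyond the
small trial-derived event-free death probability) between distant
metastasis and locoregional recurrence in the fixed proportion implied by
the published week-0 value; at $k = 0$ the published probability is
reproduced exactly. Treating the published value instead as a constant
weekly probability would keep draining the event-free state long after the
EFS hazard has reached its plateau, eliminating the cure fraction the
extrapolation was chosen to represent and roughly halving the incremental
QALY of both models; we verified this numerically before fixing the design.

### Background mortality

Age-specific background mortality comes from a bundled life table indexed
by integer age, advanced weekly from the start age (ages beyond the table
reuse its last row). In the pre-metastatic states it is combined with the
trial-derived weekly death probabilities as independent competing risks,
$1-(1-p_d)(1-p_b)$. The metastatic states use the weekly probability
derived from *all-cause* overall survival of systemic-therapy trials
directly: that quantity already contains background deaths, and combining
it with the life table again would double-count (available as the setting
`background_in_metastatic`).

The bundled table is synthetic: a Gompertz--Makeham annual hazard
$h(x) = 0.0005 + 0.0085 \cdot 2^{(x-62)/8}$ (doubling every 8 years),
converted to weekly probabilities. It reproduces a plausible adult age
gradient and a 40-year background-only survivorship from age 62 of about
5%, the lower edge of the plausibility band asserted in the tests; it is
*not* an official national life table, and any two-column CSV
(`age_years`, `weekly_mortality_probability`) can be substituted via the
configuration.

### Downstream states

Locoregional recurrence is a one-cycle tunnel: entrants incur a one-time
salvage-surgery cost, survivors move to locoregional remission the next
week. Remission carries a weekly probability of advancing to metastatic
progression-free (0.01062) and the remission death probability combined
with background mortality. In the metastatic states, progression is the
excess of PFS events over deaths, $\max(0, q_{PFS} - q_{OS})$, and death in
both metastatic states uses the OS-derived probability. The published
BRAF-group PFS/OS exponential rates already incorporate the network
meta-analysis hazard ratios weighted by each group's systemic-therapy mix
(we verified that both groups imply the same pembrolizumab reference rate
to within 0.5%); when the hazard-ratio or share inputs are perturbed in
sensitivity analyses, the rates are rescaled by the ratio of the perturbed
to the base share-weighted hazard ratio, which leaves the base case
untouched.

## Costs, utilities and accrual conventions

State membership is evaluated at cycle start with no half-cycle correction
(weekly cycles make the correction negligible). Scheduled treatment costs
(drug acquisition priced per mg, the index surgery, the expected
adverse-event cost, and the one-time BRAF test at entry) accrue only on the
fraction of the cohort still event-free at the scheduled week. Adjuvant
therapy starts `adjuvant_delay_weeks` after surgery (6 weeks in model 1,
matching the earliest protocol start; 3 weeks in model 2).

Three allocation choices deserve emphasis, because the source publication
leaves them open and they drive the totals:

* **Event-free management** (238 USD/week) accrues only on the *at-risk*
  part of event-free occupancy — total occupancy minus the cure-plateau
  survivors, whose follow-up is assumed to revert to routine care once the
  recurrence risk has died out. Charging surveillance costs to cured
  patients for up to four decades would add roughly 100,000--160,000 USD
  per arm, which is incompatible with the published totals.
* **Metastatic progression-free management**: the aggregated systemic
  therapy cost (556,052 USD per BRAF-mutant patient, 378,411 USD per
  wild-type patient, charged once on entry into metastatic
  progression-free) is taken to cover disease management during the
  on-treatment metastatic phase; weekly management is charged in the
  progression state only (1,183 USD/week). Charging the 1,102 USD/week
  progression-free management on top of the per-patient package
  double-counts and puts every arm total 25--30% above the published
  values. The alternative is available as the setting
  `mpf_management_weekly`.
* **Adverse events** are one-time expected costs and QALY decrements at
  treatment start: $\sum_e p_e \cdot \text{cost}_e$ and
  $\sum_e p_e |u_e| \cdot d/52$ with a decrement duration $d$ of 4 weeks
  (setting `ade_duration_weeks`; the sources give disutilities but no
  duration, and grade III events resolve within weeks).

QALYs weight state occupancy by the published utilities; life-years count
occupancy of the alive states. Reported life-years are discounted — across
all four arms the published QALY/LYG ratios (0.85--0.89) equal the
state-mix utility, which identifies the published life-year figures as
discounted quantities; undiscounted life-years are also computed and
exposed.

## Sensitivity analyses

**One-way:** every input is set to its published low and high bound with
all else at base, the full model re-evaluated, and the incremental net
monetary benefit ($\text{NMB} = \lambda \Delta Q - \Delta C$ at
$\lambda = 100{,}000$ USD/QALY) envelope reported in tornado order with
threshold-crossing flags. Inputs whose printed range is degenerate — the
systemic-therapy shares printed as "Fixed", and the adjuvant-nivolumab rash
probability whose printed range (0.0%--0.0%) is plainly a typo — are held
at base (the rash row gets ±20% bounds for probabilistic sampling).

**Probabilistic:** all inputs are redrawn jointly and both arms re-run
10,000 times. Parameterisations, with each printed range read as a 95%
interval so $\sigma = (\text{high}-\text{low})/3.92$:

* probabilities and utilities: beta, moment-matched to mean = base
  (disutilities sampled on their magnitude and negated); infeasible
  moments fall back to a range-truncated draw with a warning;
* hazard ratios: beta rescaled onto the printed interval, honouring the
  printed "Beta" family while allowing values above 1;
* costs: gamma, moment-matched;
* systemic-therapy shares: Dirichlet with concentration = base shares × an
  effective sample size of 100 (structural zeros stay zero);
* Gompertz shape/rate: bivariate normal with marginal SDs from the ranges
  and correlation −0.5 (setting `gompertz_correlation`), a typical value
  for Gompertz maximum-likelihood estimates; the rate is floored at a tiny
  positive value;
* PFS/OS pairs (the two rates per BRAF group and the two hazard ratios per
  therapy) are sampled **comonotonically** through a shared uniform
  quantile: the members of each pair are estimated from the same trial
  populations, and independent sampling makes about half of all draws
  incoherent (OS events outnumbering PFS events), which both triggers the
  progression clamp constantly and biases mean progression time upward.

Each draw uses its own RNG stream seeded from a draw-indexed table derived
from the master seed, so results are reproducible bit-for-bit and
independent of evaluation order; failed draws (none observed in practice)
are redrawn and counted. Summaries are means with percentile 95% intervals,
the incremental scatter, and the cost-effectiveness acceptability curve over
0--150,000 USD/QALY.

A note on the tails: in model 2 the two arms' EFS curves are sampled
independently (each arm has its own published fit), so in roughly 0.2% of
draws the sampled cure plateaus invert and the perioperative strategy is
not cost-effective at 100,000 USD/QALY; the acceptability curve sits at
~99.8% rather than exactly 100%. Model 1 is structurally protected because
its perioperative EFS is tied to the shared adjuvant fit through a sampled
hazard ratio that is below 1 almost surely.

## Survival estimation tools and synthetic data

The package also contains the estimation pipeline that produced inputs of
this kind: `simulate_ipd()` draws individual event/censoring times from a
Gompertz curve by inverse transform (plateau draws are administratively
censored; uniform accrual shortens follow-up), `make_km_points()`
summarises them as Kaplan--Meier coordinates with a risk table,
`reconstruct_ipd()` inverts published coordinates back into pseudo
individual-patient data (the single-interval special case of the standard
reconstruction algorithm: events are assigned to the risk set at each
published drop, risk-set deficits between coordinates become mid-interval
censorings, and the bookkeeping telescopes exactly to the initial cohort
size), and `fit_parametric()` fits Gompertz/exponential/Weibull models by
maximum likelihood (via `flexsurv`) with BIC selection
(`select_by_bic()`, ties to the smaller family). Property tests recover
all four published parameter pairs within 3 standard errors through the
full simulate → KM → reconstruct → fit pipeline at n = 2000.

The generator emulates administrative censoring and uniform accrual only;
it does not emulate covariate-dependent risks, dropout, or interim-analysis
censoring patterns, so passing tests demonstrate correctness of the
estimation machinery, not robustness to every real-trial artefact.

## Numerical choices and degenerate inputs

* Gompertz shapes within $10^{-8}$ of zero switch to a series expansion
  (survival) and the exponential limit (cycle probabilities) to avoid 0/0.
* The residual locoregional-recurrence probability, the metastatic
  progression probability, and the at-risk event-free occupancy are clamped
  at zero; clamps warn (outside Monte Carlo loops) because they are exactly
  where reproduction of the published table could drift.
* Transition rows are validated to sum to 1 within $10^{-12}$; the C++
  cohort kernel aborts if occupancy conservation degrades beyond $10^{-9}$.
* Monetary results are rounded to whole dollars and QALYs/life-years to
  two decimals only in the reporting layer.

## Problem sizes

The deterministic base case is a 2080-cycle evaluation of 2--6
subgroup cohorts per arm and runs in well under a second. The probabilistic
analysis re-evaluates both arms 10,000 times per model (the published
simulation count) in a few minutes on one CPU, with the cycle loop in
compiled code. Test fixtures use 200--20,000 synthetic subjects for the
estimation pipeline.

## Known limitations

* The published base-case table cannot be decomposed exactly from the
  published inputs under any accrual convention we tried; the three
  allocation choices above reproduce totals, QALYs, life-years and
  increments to within ±15% (most cells within ±8%), but individual
  breakdown cells (notably the surgery column and the before-recurrence
  column) remain discrepant, and the neoadjuvant cost cell of the
  perioperative nivolumab+ipilimumab arm exceeds raw two-cycle drug cost
  arithmetic in the source itself.
* Three printed utility rows (locoregional remission, metastatic
  progression-free, metastatic disease progression) have base values
  outside their own printed sensitivity ranges; validation flags them and
  the printed values are used unchanged.
* The model inherits the source's structure: no treatment discontinuation
  or dose modification, no vial wastage, no indirect costs, and a pairwise
  (not multi-strategy) comparison per model.
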