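---
title: "Cost-utility analysis with a DAS-28 Markov cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility analysis with a DAS-28 Markov cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
library(dplyr)
```

## The model

`markovcea` evaluates competing treatment strategies for a chronic disease
with a discrete-time Markov cohort model. The motivating application is
rheumatoid arthritis treated with TNF inhibitors (Infliximab, Adalimumab,
Etanercept), where disease activity is staged by the 28-joint Disease
Activity Score (DAS-28). The model's five health states are the four
standard DAS-28 bands plus an absorbing Death state:

| State     | DAS-28 band | Notes                              |
|-----------|-------------|------------------------------------|
| Remission | < 2.6       |                                    |
| Low       | 2.6 – 3.2   |                                    |
| Moderate  | 3.2 – 5.1   |                                    |
| Severe    | > 5.1       | usual threshold to start a biologic |
| Death     | n/a         | absorbing; zero cost, zero utility |

A cohort starts from an initial distribution over the living states and
moves through a validated row-stochastic transition matrix $P$ once per
cycle: if $\pi_t$ is the occupancy row vector at cycle $t$, then
$\pi_{t+1} = \pi_t P$. Published transition tables usually omit the terminal
row, so `as_transition_matrix()` accepts the four living-state rows and
appends the absorbing row $(0,0,0,0,1)$; `validate_matrix()` enforces
entries in $[0,1]$, row sums of 1 within $10^{-9}$, and the absorbing Death
row.

Discounted totals per strategy are

$$
\mathrm{Cost} = \sum_{t}\sum_{s} \pi_{t,s}\, c_s\, (1+r_c)^{-t\Delta},
\qquad
\mathrm{QALY} = \sum_{t}\sum_{s} \pi_{t,s}\, u_s\, \Delta\, (1+r_o)^{-t\Delta},
$$

with cycle length $\Delta$ (years), per-cycle state cost $c_s$, state
utility $u_s$, and separate annual discount rates for costs ($r_c$) and
outcomes ($r_o$). Because both totals are linear in the occupancy trace,
the engine folds the trace and discounting into per-state weights once and
reuses them for the deterministic evaluation, the tornado, and every PSA
draw — the draws differ only in $c_s$ and $u_s$, never in $P$.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `cycle_length_years` | years | 0.25 | quarterly clinical review is the standard RA cycle |
| `discount_rate_costs` | fraction / year | 0.058 | local economic-evaluation guidance for costs |
| `discount_rate_outcomes` | fraction / year | 0.03 | conventional outcome discounting |
| `max_cycles` | cycles | 400 | 100 years, a lifetime-horizon proxy; the trace also stops early once living mass < $10^{-9}$ |
| `initial_distribution` | probability vector | 100% Severe | biologics are initiated above DAS-28 5.1; configurable because source studies rarely state it |
| `half_cycle_correction` | logical | `FALSE` | off unless requested, matching common decision-tree software behaviour |
| `gdp_per_capita` | PPP $ | 12,547 | willingness-to-pay anchor (2019) |
| `wtp_multipliers` | — | (1, 3) | WHO rule: < 1×GDP/QALY highly cost-effective, < 3× cost-effective |
| `cost_cv` (PSA, synthesis) | — | 0.2 | cost SDs are not part of the base set; a 20% coefficient of variation mirrors the one-way perturbation scale |

Two deliberately open modelling choices are exposed as configuration rather
than guessed as fixed truth: the starting distribution, and whether costs
are state-dependent. By default the annual cost total is spread uniformly
over living states ($c_s = \text{annual total} \times \Delta$); an optional
`state_cycle_costs` table overrides this per strategy when state-specific
costing is available.

### Reward attribution and discounting

Rewards are attributed to the occupancy at the start of each cycle: row $t$
of the trace pays cycle $t$'s cost and utility, including the final row.
With `half_cycle_correction = TRUE` the engine instead averages adjacent
occupancy rows, the standard mid-cycle approximation. Discounting is
continuous in cycles — elapsed time is $t\Delta$ years — which is exact at
year boundaries and smooth between them.

## Ranking, dominance, and thresholds

`rank_strategies()` sorts strategies by ascending cost and applies the
standard efficiency-frontier analysis:

* **absolute dominance** (including weak dominance): another strategy costs
  no more and yields at least as many QALYs, strictly better in one;
  identical pairs break by name order for determinism;
* **extended dominance**: among survivors ordered by cost, a strategy whose
  incremental ICER against the previous survivor exceeds the ICER of the
  next survivor against itself lies above the convex frontier and is
  removed, iterating until the ICER sequence is nondecreasing;
* the cheapest survivor is the reference; remaining survivors carry
  sequential ICERs. Nondominated rows report increments against the
  previous frontier strategy; dominated rows report increments against the
  reference, the layout used in published three-way comparisons.

With the bundled three-strategy table and one absolutely dominated
strategy, extended dominance cannot fire — the test suite asserts exactly
that — but the implementation handles the general case and is checked
against a brute-force convex-combination oracle on random instances.

An ICER with equal outcomes in the denominator is undefined and returned as
`NA`; dominance by cost alone then decides. `classify_icer()` applies the
GDP bands with exclusive upper bounds: `highly_cost_effective` strictly
below 1×GDP, `cost_effective` from 1× up to but excluding 3×,
`not_cost_effective` at or above 3×.

## One-way sensitivity analysis

`run_owsa()` perturbs every cost component and every living-state utility
mean of the two compared strategies to ×0.8 and ×1.2 of its base value, one
at a time, re-evaluating the pairwise ICER at each endpoint. Entries are
sorted by descending width $|ICER_{high} - ICER_{low}|$; parameters with no
influence (for example a zero-cost component) keep zero-width bars at the
tail. Utility perturbations are applied as-is even when ×1.2 pushes a mean
above 1: the tornado is a deterministic what-if on the mean, not a draw
from the utility distribution, so the $[0,1]$ validation of stored
parameters deliberately does not apply. Because costs enter the ICER
numerator linearly with the QALY gap fixed, the two endpoints of a cost bar
sit symmetrically around the base — a property the tests check numerically.

## Probabilistic sensitivity analysis

`run_psa()` implements second-order Monte Carlo: each trial draws one value
for every parameter and evaluates all strategies on the shared draw; there
is no patient-level (first-order) noise. Distributions are moment-matched:

* utilities on $[0,1]$ use a beta with
  $\nu = m(1-m)/s^2 - 1$, $\alpha = m\nu$, $\beta = (1-m)\nu$ — feasible
  only when $s^2 < m(1-m)$; infeasible inputs abort before any sampling
  with the feasibility bound in the message;
* nonnegative costs use a gamma with shape $m^2/s^2$ and rate $m/s^2$,
  with $s = 0.2\,m$ by default (`cost_cv`).

A zero SD is treated as a degenerate point mass, so setting every SD to
zero reproduces the deterministic table exactly — a test asserts this.
Sampling order is fixed (strategies alphabetically, then utility states,
then cost components alphabetically) and a single seeded generator drives
the run, so results are bit-reproducible from the seed. When a strategy
uses `state_cycle_costs`, sampled component totals scale the state costs
proportionally, preserving the configured state pattern.

`ceac()` computes, per willingness-to-pay value, each strategy's
probability of having the maximal net monetary benefit
($\mathrm{NMB} = \mathrm{QALY}\times\mathrm{WTP} - \mathrm{Cost}$), ties
split equally; the default grid runs from 0 to 3×GDP in 100 steps and
always contains 1×GDP. `acceptance_fraction()` uses strict inequality on
the incremental NMB, so identical strategies score 0, not 0.5 — a
documented tie convention.

## The synthetic cohort generator

`generate_cohort()` emulates the patient-level structure the arm summaries
assume: per arm, a categorical DAS-28 outcome band (multinomial on the
arm's response counts), a per-band beta utility, and per-component gamma
costs, all sampled independently. The bundled response table records the
three outcome categories reported for each arm; the residual "above 3.2"
category is mapped to the Moderate band with zero mass in Severe, reading a
post-treatment score that stayed above the biologic-initiation threshold as
moderate rather than unchanged-severe. The generator does **not** simulate:

* the EQ-5D instrument or a national tariff (utilities are drawn directly
  on the band scale);
* correlation between cost components, or between costs and utilities;
* covariates (age, sex), dropout, or missing data.

Passing round-trip tests therefore show that the estimation pipeline is
consistent for independently sampled band-level data — not that real
interview data meet those independence assumptions.

`summarize_arm()` reports band counts and percentages (2 decimals),
per-band utility mean and sample SD ($n-1$; a single patient reports SD 0
with a degenerate flag), and cost components with within-category shares —
the categories being direct medical (DMC), direct nonmedical (DNMC), and
indirect (IC) costs, which always satisfy DMC + DNMC + IC = total.
`recover_parameters()` closes the loop, flagging bands with too few
patients instead of imputing them.

The recovery study in the acceptance suite uses 25 independent replicate
cohorts of 10,000 patients per arm and compares replicate-averaged
estimates to the generating values within ±0.01. Averaging over replicates
is what makes the ±0.01 bound a genuine bias check: the rarest band in the
bundled set holds ~4% of an arm, so a single cohort's band-utility estimate
carries a Monte Carlo standard error above 0.01 by itself.

## Numerical choices and degenerate inputs

* Row-sum tolerance $10^{-9}$; early-stop living-mass tolerance $10^{-9}$.
* Equal-cost/equal-QALY ties break by name; CEAC argmax ties split equally;
  acceptance fractions use strict inequality.
* `icer()` returns `NA` (undefined) on equal outcomes rather than ±Inf.
* Serialized tables carry 6 significant digits; percentages print at 2
  decimals.
* The bundled Etanercept direct-medical components sum to 10,686.19 against
  a source total of 10,677.20; components are stored as given and totals
  recomputed from components, with the 8.99 discrepancy flagged in a
  `notes` attribute rather than silently reconciled.

The unit tests run the engine on truncated horizons (30–100 cycles) and
the full suite completes in under a minute; the acceptance suite uses the
full 400-cycle horizon, a 5,000-draw PSA, and the 25 × 10,000-patient
recovery study described above.

## Known limitations

* No background (life-table) mortality: the only death pathway is the
  transition matrix's Death column, so overall survival is governed
  entirely by the disease-state hazards.
* Cohort expectation only — no microsimulation mode.
* The PSA samples utilities and costs but not transition probabilities.
* Published three-way comparisons of these biologics report strategy-level
  totals whose internal settings (starting distribution, state-cost
  mapping, distribution variances) are typically not printed; the package
  exposes those settings as configuration so users can explore scenarios,
  and no bundled configuration is claimed to reproduce any particular
  published total.
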