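---
title: "Methods: decision-tree cost-effectiveness analysis of screening tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness analysis of screening tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screencea)
```

## The decision problem

Two point-of-care tests compete for one screening slot: which should a
health system buy? `screencea` answers this for a single screening cycle
with a decision tree. A decision node chooses the strategy; a chance node
splits the cohort by disease status at prevalence $p$; a second chance node
draws the test result — positive with probability $Se$ given disease,
negative with probability $Sp$ given none. Terminals carry a payoff pair:
the strategy's societal unit cost, and an effectiveness of 1 for a correct
diagnosis (true positive or true negative) and 0 otherwise. The reference
standard that defines "correct" is represented implicitly — it decides
which branch is which, and is not costed, since it is a study instrument
rather than part of either strategy.

Rollback (probability-weighted expectation from leaves to root) gives each
strategy an expected cost equal to its unit cost and an expected
effectiveness

$$E = p\,Se + (1-p)\,Sp,$$

the proportion correctly diagnosed. Effectiveness is deliberately *not* a
QALY: the analytic horizon ends at the diagnostic decision, so downstream
treatment and complications are out of scope. The payoff pair is kept
extensible so outcome-specific costs or other effect measures could be
attached to terminals.

## Worked example and its parameters

The bundled configuration (`example_path("config")`) encodes a comparison
of HbA1c and fasting plasma glucose (FPG) point-of-care screening in a
Ugandan outpatient cohort. All parameters are dimensionless fractions
except unit costs (USD per test):

| parameter | base | range | note |
|---|---|---|---|
| prevalence $p$ | 0.084 | 0.0709–0.0982 | 95% CI bounds |
| HbA1c $Se$ | 0.698 | 0.463–0.861 | |
| HbA1c $Sp$ | 0.986 | 0.954–0.996 | |
| FPG $Se$ | 0.626 | 0.415–0.798 | |
| FPG $Sp$ | 0.994 | 0.989–0.997 | |
| HbA1c unit cost | 6.922 | — | societal |
| FPG unit cost | 8.188 | — | societal |

```{r base-case}
model <- config_to_model(load_config(example_path("config")))$model
evaluate_cea(model)
```

## Microcosting

Unit costs are built bottom-up from an ingredient table: each component is
either a study-period total spread over `n_tests` or a unit price times a
per-test quantity. Choices made where the costing design was open:

* **Costing denominator.** `n_tests = 1659` for both strategies — the
  denominator implied by the published totals divided by unit costs — even
  though only a subsample received the second test in the underlying
  accuracy study. Costs answer "what would testing everyone cost", not
  "what did the study spend".
* **Capital annualization.** `annualize_capital()` uses the annuity factor
  $(1-(1+r)^{-L})/r$, with the straight-line limit $L$ at $r = 0$. The
  default discount rate is 0 because a single testing cycle lasting minutes
  gives nothing to discount; the rate is configurable since costing
  guidelines conventionally use a positive one. Note the annualized value
  exceeds the acquisition cost at $L = 1$ with $r > 0$ (the payment carries
  a year's interest); it falls below it from $L \ge 2$ at the rates used
  here.
* **Patient components carry their own trip multipliers.** The FPG
  strategy's extra fasted-state visit doubles its transport component while
  meals and lost productivity scale by 1.5; each patient ingredient
  therefore has its own `trips_multiplier` rather than one global visit
  factor, and the published per-test values are taken as direct inputs
  rather than re-derived. Furniture, space and record-keeping costs are
  excluded (identical across strategies).
* **Source-table inconsistency.** In the published costing table the
  patient-cost subtotal row disagrees with the sum of its own component
  totals, and the abstract's unit costs ($6.48/$8.39) disagree with the
  table's ($6.922/$8.188). The unit-cost columns are internally consistent
  and only they reproduce the published ICER, so they are treated as
  authoritative: the component CSV reproduces them to within 0.001 (the
  residual is the source's own rounding), and the canonical unit costs
  6.922/8.188 enter the decision model as explicit config inputs.
  `cer()` computes cost/effectiveness; the abstract's $6.74 ratio is
  recovered only with the unexplained 6.48 cost and is documented, not
  matched.
* **Currency.** Values are stored full-precision in USD and rounded only at
  report time (currency 2 dp, proportions 3 dp, percentages 1 dp).
  `convert_currency()` applies rate and inflation factor; the bundled
  fixture uses factor 1 with report-year USD taken as given.

## Ranking and dominance

`rank_and_compare()` sorts by ascending cost. Absolute dominance
(cheaper-or-equal and strictly more effective, or equally effective and
strictly cheaper) is a pairwise check; extended dominance is applied
iteratively — a strategy is removed when the ICER of reaching it exceeds
the ICER of moving past it, i.e. when a blend of its neighbours on the
frontier beats it. ICERs are attached between successive survivors, so the
surviving ICER sequence is strictly increasing by construction; the tests
verify both rules against an independent brute-force frontier (blend
feasibility checked from first principles). The ICER is sign-invariant
under swapping its arguments; we canonically attach it to the costlier
strategy and record direction in the ordering. Effectiveness differences
below $10^{-12}$ are treated as ties (no ICER; the cost difference is
reported alongside).

## Sensitivity, threshold and scenario analyses

`one_way_dsa()` re-evaluates the full pipeline over a grid across one
parameter's uncertainty range (default 101 points, endpoints included),
recording endpoint and extreme ICERs. When the incremental effectiveness or
cost changes sign inside the range the ICER passes through a singularity
and a min/max across it is meaningless; the row instead reports the
dominance-region boundary, located by root-finding (`uniroot`, tolerance
$10^{-9}$) on the quantity whose sign flips.

`threshold_equal_effectiveness()` solves $E_A(\theta) = E_B$ in closed form
— effectiveness is linear in each of $p$, $Se$, $Sp$ — with a bisection
fallback (tolerance $10^{-9}$, bracket required; an unbracketed parameter
returns a no-threshold result, not an error). Closed form and bisection are
cross-checked in the tests to $10^{-8}$, and every solved tie-point is
re-verified by re-evaluating both strategies at it (difference $<
10^{-9}$). For the worked example the four accuracy tie-points are 71.3%,
98.7%, 61.1% and 99.3%, each inside its uncertainty range; the prevalence
tie-point (10.0%) falls outside its range, so the base-case ranking is
robust to prevalence. Accuracy parameters tie *effectiveness*; the
transport parameter ties *cost* (`transport_tie_point()` solves
$t^\* = (\text{nontransport}_B - \text{nontransport}_A)/(\text{visits}_A -
\text{visits}_B)$, $0.067 per trip here); the tied quantity is explicit in
every result. Thresholds are displayed at 1 decimal in percent.

`scenario_provider_cost()` swaps one strategy's provider per-test cost
while holding its patient costs (taken from the ingredient profile) and all
accuracy parameters fixed.

```{r scenario}
scenario_provider_cost(model, "HBA1c", 0.781)
```

Two published sensitivity results are deliberately not reproduced: the
prevalence-DSA ICER interval and the parallel-instrument scenario ICERs.
Neither follows from the printed inputs under the stated linear model (the
closed-form prevalence endpoints differ several-fold from the published
interval, and the cost decomposition under instrument parallelism is not
specified), so the package asserts only the analytically derivable
properties of those analyses.

## The cohort simulator

`simulate_cohort()` is the Monte-Carlo twin of the tree: disease status
Bernoulli($p$), result Bernoulli($Se$) given disease and positive with
probability $1-Sp$ otherwise, individuals cross-classified into TP/FP/TN/FN
with the strategy's unit cost accrued. `empirical_comparison()` uses common
random numbers — the two strategies share the drawn disease statuses, with
independent result draws — which removes the prevalence component from the
variance of the effectiveness difference and makes tolerances derivable
from the status-conditional binomial variance. A single user seed expands
into independent substream seeds (status, then one per strategy) so adding
a strategy never perturbs earlier draws; identical inputs and seed give
byte-identical summaries. The proportion-correct CI is a Wilson score
interval, whose coverage degrades less than Wald's at proportions near 1
(the regime here, $E \approx 0.96$).

The generator emulates exactly the statistical structure the tree assumes:
independent individuals, fixed accuracy, a single cycle. It does not
emulate result-based two-stage sampling, spectrum effects, imperfect
reference standards or missed return visits — so passing simulation checks
validates the arithmetic of the model, not those aspects of real screening
data.

## Verification scale and numerical conventions

The test suite verifies rollback against the closed form (and exhaustive
path enumeration on trees with rational probabilities) on 1,000 randomly
generated two-strategy models to $10^{-12}$; recovers the analytic
effectiveness within 3 binomial SE in at least 99 of 100 seeded cohorts of
$10^5$; checks one seeded two-strategy comparison at $10^6$ individuals
against the analytic ICER within the 3-SE band implied by the
common-random-numbers variance; and compares dominance classification with
the brute-force frontier on 300 random strategy sets of up to six
strategies. Chance-node probabilities must sum to 1 within $10^{-9}$
absolute; effectiveness ties use $10^{-12}$; threshold solutions and
re-verification use $10^{-9}$.

## Limitations

Effectiveness stops at the diagnostic decision: no treatment uptake, QALYs
or complication modelling, and no confirmatory-sequence strategies
(test-then-retest algorithms). Probabilistic sensitivity analysis is not
implemented — parameter uncertainty enters only through one-way ranges and
thresholds. The extended-dominance pruner assumes the usual frontier
semantics (blends of adjacent strategies are feasible), which may not hold
where strategies cannot be mixed across a population.
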