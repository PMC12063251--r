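# screencea

Decision-tree cost-effectiveness analysis of diagnostic screening tests, for
health economists and epidemiologists evaluating point-of-care diagnostics.
The package implements the full desk-scale pipeline: ingredient-based
(bottom-up) microcosting from a societal perspective, a decision-tree model
of screening outcomes with expectation rollback, incremental
cost-effectiveness ratios (ICERs) with absolute and extended dominance
handling, one-way deterministic sensitivity / threshold / scenario analyses,
and a Monte-Carlo cohort simulator that stochastically verifies the analytic
results.

## The model

A screening strategy with sensitivity *Se*, specificity *Sp* and societal
unit cost *C* is applied to a population with disease prevalence *p*. Each
screened person falls into one of four outcomes:

| outcome | probability | effectiveness payoff |
|---|---|---|
| true positive | p·Se | 1 |
| false negative | p·(1−Se) | 0 |
| true negative | (1−p)·Sp | 1 |
| false positive | (1−p)·(1−Sp) | 0 |

Rolling the tree back gives each strategy an expected cost *C* and an
expected effectiveness — the proportion correctly diagnosed —

E = p·Se + (1−p)·Sp.

For two strategies A (cheaper) and B the incremental cost-effectiveness
ratio is

ICER = (C_B − C_A) / (E_B − E_A),

in currency per additional person correctly diagnosed. A strategy that is
costlier and less effective is absolutely dominated; with three or more
strategies, extended dominance prunes any strategy that a blend of its
neighbours beats on the cost-effectiveness frontier.

Unit costs come from ingredient-based microcosting: every input consumed by
a single test (staff minutes, kits, consumables, power, equipment time —
capital items annualized over their useful life) plus the patient-borne
costs a societal perspective adds (transport, meals, lost productivity).

## Worked example

The bundled configuration compares point-of-care HbA1c and fasting plasma
glucose (FPG) screening for type 2 diabetes in a Ugandan outpatient cohort
of 1659 adults (prevalence 8.4%). FPG requires a return visit in a fasted
state, which doubles the patient's transport exposure; HbA1c needs one
visit but a costlier analyser and more staff time.

```r
library(screencea)

cfg   <- load_config(example_path("config"))
model <- config_to_model(cfg)$model
evaluate_cea(model)
#> Cost-effectiveness ranking (ascending cost)
#>  strategy cost effectiveness incremental_cost incremental_effectiveness   icer        status
#>     HBA1c 6.92         0.962               NA                        NA     NA      baseline
#>       FPG 8.19         0.963             1.27                     0.001 989.06 non-dominated
```

HbA1c costs $6.922 per test and correctly classifies 96.2% of those
screened; FPG costs $8.188 and classifies 96.3% correctly. Moving from
HbA1c to FPG therefore buys each extra correct diagnosis at an ICER of
$989.06. Threshold analysis locates the accuracy values at which the two
strategies tie:

```r
threshold_equal_effectiveness(model, "HBA1c.sensitivity")
#> <threshold_result> HBA1c.sensitivity ties effectiveness at 0.7132 (within uncertainty range)
```

so a modest sensitivity gain (69.8% → 71.3%) would make HbA1c the more
effective *and* cheaper option. Scenario analysis answers provider-cost
what-ifs — a cheaper HbA1c analyser matching the FPG provider cost of
$0.781 per test raises the ICER to $2,276.56 — and the transport tie-point
shows FPG becomes the cheaper strategy only if a one-way trip costs less
than $0.07. `run_pipeline(cfg, "reports")` writes the full CSV/JSON report
bundle, and `simulate_cohort()` / `empirical_comparison()` reproduce the
expected values by individual-level simulation.

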