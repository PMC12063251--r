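# Point-of-care diabetes screening comparison, Iganga general hospital
# outpatient cohort (costing base date 2019-06-01). Societal perspective,
# single screening cycle of 1659 adults.
currency:
  exchange_rate: 3789.58     # UGX per USD on 2019-06-01
  inflation_factor: 1.0      # unit costs are taken as given in report-year USD
costing:
  n_tests: 1659
  discount_rate: 0.0         # single short testing cycle: no discounting
  ingredient_table: iganga_2019_costs.csv
cohort:
  prevalence: 0.084
  range: [0.0709, 0.0982]
tests:
  - name: HBA1c
    sensitivity: 0.698
    sens_range: [0.463, 0.861]
    specificity: 0.986
    spec_range: [0.954, 0.996]
    unit_cost: 6.922         # societal unit cost, USD per test
    n_visits: 1              # no fasting required: tested on the spot
  - name: FPG
    sensitivity: 0.626
    sens_range: [0.415, 0.798]
    specificity: 0.994
    spec_range: [0.989, 0.997]
    unit_cost: 8.188
    n_visits: 2              # return trip in a fasted state
analysis:
  dsa:
    parameters:
      - prevalence
      - HBA1c.sensitivity
      - HBA1c.specificity
      - FPG.sensitivity
      - FPG.specificity
    grid_points: 101
  thresholds:
    - HBA1c.sensitivity
    - HBA1c.specificity
    - FPG.sensitivity
    - FPG.specificity
  scenarios:
    - strategy: HBA1c
      provider_cost: 0.781   # HBA1c provider cost lowered to the FPG level
  transport_tie:
    a: FPG
    b: HBA1c
  simulation:
    n: 100000
    seed: 20190601
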