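# Base-case configuration of the five-state fall prevention
# cost-effectiveness model. Read with read_model_config().
config:
  cohort_size: 173
  start_age: 76
  horizon: 12
  discount_rate: 0.03
  half_cycle: true
  discount_first_year: false
  effect_duration: 1
  initial_state: A

# Annual transition probabilities, no-intervention arm.
# Rows are origin states, columns destinations, order A B C D E.
transition_matrix:
  A: [0.72, 0.07, 0.13, 0.05, 0.03]
  B: [0.59, 0.13, 0.20, 0.05, 0.03]
  C: [0.28, 0.09, 0.20, 0.23, 0.20]
  D: [0.00, 0.00, 0.00, 0.60, 0.40]
  E: [0.00, 0.00, 0.00, 0.00, 1.00]

# Annual quality-of-life weight and societal cost (EUR) per state.
payoffs:
  utility: {A: 0.86, B: 0.72, C: 0.59, D: 0.41, E: 0.0}
  cost:    {A: 0,    B: 707,  C: 18625, D: 99727, E: 0}

intervention:
  rate_ratio: 0.76          # 24% reduction in the rate of falls, first year
  effect_duration: 1
  rounding: table           # first-year matrix rounded to whole percent
  cost_components:          # totals in EUR, spread over the cohort
    - {label: brochure,                 category: recruitment, total: 6707, units: 7500}
    - {label: bus advertisement,        category: recruitment, total: 1600, units: 64}
    - {label: oral presentations,       category: recruitment, total: 600,  units: 23}
    - {label: group exercise sessions,  category: support,     total: 6900, units: 30}
    - {label: drop-in support meetings, category: support,     total: 256,  units: 10}
    - {label: application maintenance,  category: maintenance, total: 4581}

# Background mortality: exponential growth in the annual death probability,
# anchored to the baseline A->E probability at the start age.
mortality_schedule:
  type: gompertz
  anchor: 0.03
  slope: 0.08
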