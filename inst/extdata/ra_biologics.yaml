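# Parameter set: Infliximab vs Adalimumab vs Etanercept for rheumatoid
# arthritis, societal perspective, 2019 PPP dollars.
# States follow DAS-28 bands: Remission (< 2.6), Low (2.6-3.2),
# Moderate (3.2-5.1), Severe (> 5.1), plus absorbing Death.
# Response counts place each arm's patients in the band reached on
# treatment; residual "> 3.2" outcomes are recorded as Moderate.
model:
  cycle_length_years: 0.25
  discount_rate_costs: 0.058
  discount_rate_outcomes: 0.03
  max_cycles: 400
  initial_distribution:
    Remission: 0.0
    Low: 0.0
    Moderate: 0.0
    Severe: 1.0
    Death: 0.0
  half_cycle_correction: false
  gdp_per_capita: 12547.0
  wtp_multipliers: [1, 3]
transitions:
  file: ra_transitions.csv
strategies:
  - name: Infliximab
    n_patients: 53
    annual_costs:
      visits: 172.14
      medication: 7110.39
      tests: 618.40
      physiotherapy_other: 410.41
      diagnostics: 284.96
      injection: 407.70
      transportation: 1451.79
      accommodation: 580.92
      meals: 451.96
      lost_revenue: 186.53
    utilities:
      Remission: {mean: 0.836, sd: 0.196}
      Low: {mean: 0.717, sd: 0.148}
      Moderate: {mean: 0.23, sd: 0.216}
      Severe: {mean: 0.2, sd: 0.170}
    response:
      Remission: 27
      Low: 17
      Moderate: 9
      Severe: 0
  - name: Adalimumab
    n_patients: 48
    annual_costs:
      visits: 172.14
      medication: 8582.42
      tests: 618.40
      physiotherapy_other: 387.60
      diagnostics: 284.96
      injection: 0.00
      transportation: 1285.51
      accommodation: 435.22
      meals: 378.74
      lost_revenue: 192.62
    utilities:
      Remission: {mean: 0.725, sd: 0.193}
      Low: {mean: 0.656, sd: 0.223}
      Moderate: {mean: 0.437, sd: 0.209}
      Severe: {mean: 0.23, sd: 0.190}
    response:
      Remission: 33
      Low: 2
      Moderate: 13
      Severe: 0
  - name: Etanercept
    n_patients: 53
    annual_costs:
      visits: 172.14
      medication: 9171.32
      tests: 618.40
      physiotherapy_other: 439.37
      diagnostics: 284.96
      injection: 0.00
      transportation: 318.02
      accommodation: 125.22
      meals: 113.52
      lost_revenue: 172.82
    utilities:
      Remission: {mean: 0.891, sd: 0.126}
      Low: {mean: 0.337, sd: 0.276}
      Moderate: {mean: 0.391, sd: 0.211}
      Severe: {mean: 0.223, sd: 0.190}
    response:
      Remission: 29
      Low: 5
      Moderate: 19
      Severe: 0
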