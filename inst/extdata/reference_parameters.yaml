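clinical:
  entry_age:
    base: 66.0
    low: 61.0
    high: 69.0
    dist: normal
    kind: ci95
  baseline_hosp_rate:
    base: 1.13
    low: 0.68
    high: 1.55
    dist: gamma
    kind: ci95
  hr_hosp_treatment:
    base: 0.48
    low: 0.38
    high: 0.67
    dist: lognormal
    kind: ci95
  baseline_mortality_12m_treatment:
    base: 0.16
    low: 0.14
    high: 0.18
    dist: beta
    kind: ci95
  hr_mortality_admission:
    base: 3.32
    low: 1.0
    high: 5.0
    dist: lognormal
    kind: ci95
  p_complication:
    base: 0.03
    low: 0.02
    high: 0.04
    dist: beta
    kind: ci95
  p_procedural_death:
    base: 0.004
    low: 0.003
    high: 0.005
    dist: beta
    kind: ci95
utility:
  utility_baseline:
    base: 0.711
    sd: 0.027
    dist: beta
    kind: sd
  du_treat_1_6:
    base: 0.001
    sd: 0.001
    dist: normal
    kind: sd
  du_treat_7_60:
    base: 0.003
    sd: 0.003
    dist: normal
    kind: sd
  du_ctrl_1_6:
    base: -0.005
    sd: 0.004
    dist: normal
    kind: sd
  du_ctrl_7_60:
    base: -0.003
    sd: 0.003
    dist: normal
    kind: sd
  disutility_admission:
    base: 0.045
    sd: 0.012
    dist: beta
    kind: sd
costs:
  cost_device:
    base: 1392182.0
    low: 1044137.0
    high: 1740228.0
    dist: normal
    kind: minmax
  cost_implant:
    ss:
      base: 100878.0
      low: 75659.0
      high: 126098.0
      dist: normal
      kind: minmax
    ps:
      base: 137090.0
      low: 102818.0
      high: 171363.0
      dist: normal
      kind: minmax
  cost_complication_weighted:
    ss:
      base: 144482.0
      low: 108362.0
      high: 180603.0
      dist: normal
      kind: minmax
    ps:
      base: 193445.0
      low: 145084.0
      high: 227954.0
      dist: normal
      kind: minmax
  cost_monitoring_monthly:
    ss:
      base: 973.0
      low: 730.0
      high: 1217.0
      dist: normal
      kind: minmax
    ps:
      base: 1502.0
      low: 1126.0
      high: 1877.0
      dist: normal
      kind: minmax
  cost_standard_care_monthly:
    ss:
      base: 4512.0
      low: 3384.0
      high: 5641.0
      dist: normal
      kind: minmax
    ps:
      base: 5440.0
      low: 4080.0
      high: 6800.0
      dist: normal
      kind: minmax
  cost_admission:
    ss:
      base: 362788.0
      low: 272091.0
      high: 453485.0
      dist: normal
      kind: minmax
    ps:
      base: 534983.0
      low: 401237.0
      high: 655753.0
      dist: normal
      kind: minmax
structural:
  discount_rate_annual: 0.05
  effect_duration_months: 60.0
  calibration_target_mortality: 0.23
  calibration_horizon_months: 18.0
  gdp_per_capita: 700473.0
  exchange_rate_ars_per_usd: 76.95
  utility_mode: carry_forward
  monitoring_duration_months: '.inf'
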