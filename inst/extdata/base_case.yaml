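# Base-case inputs of the decision model: monthly transition probabilities,
# costs (USD, 2021 prices), utilities, PSA ranges/SDs/distribution families,
# the age-banded monthly non-cardiovascular mortality table, the 2015-2021
# healthcare CPI chain and the 2021 average CNY/USD exchange rate.
settings:
  start_age: 60
  horizon_cycles: 480
  discount_annual: 0.03
  wtp_usd_per_qaly: 37654.5
parameters:
  p_cvd_early_sv:   {base: 0.0114, low: 0.0044, high: 0.0185, sd: 0.0035, family: beta}
  p_cvd_early_ena:  {base: 0.0172, low: 0.0086, high: 0.0258, sd: 0.0044, family: beta}
  p_cvd_late_sv:    {base: 0.0053, low: 0.0048, high: 0.0057, sd: 0.0002, family: beta}
  p_cvd_late_ena:   {base: 0.0066, low: 0.0061, high: 0.0071, sd: 0.0003, family: beta}
  p_hosp_early_sv:  {base: 0.0406, low: 0.0275, high: 0.0539, sd: 0.0067, family: beta}
  p_hosp_early_ena: {base: 0.0717, low: 0.0545, high: 0.0893, sd: 0.0089, family: beta}
  p_hosp_late_sv:   {base: 0.0256, low: 0.0228, high: 0.0285, sd: 0.0014, family: beta}
  p_hosp_late_ena:  {base: 0.0339, low: 0.0306, high: 0.0373, sd: 0.0017, family: beta}
  cost_sv_month:    {base: 50.5,   low: 25.2,   high: 180.7,  sd: 18,     family: gamma}
  cost_ena_month:   {base: 37.9,   low: 18.9,   high: 75.7,   sd: 3.8,    family: gamma}
  cost_hosp_event:  {base: 2361.5, low: 1180.7, high: 4722.9, sd: 236,    family: gamma}
  u_sv_month:       {base: 0.0698, low: 0.0628, high: 0.0768, sd: 0.0036, family: beta}
  u_ena_month:      {base: 0.0691, low: 0.0622, high: 0.076,  sd: 0.0035, family: beta}
  u_hosp_event:     {base: -0.1,   low: -0.13,  high: -0.08,  sd: 0.0128, family: beta}
  discount_annual:  {base: 0.03,   low: 0,      high: 0.06,   sd: null,   family: null}
life_table:
  age_breaks:   [60, 65, 70, 75, 80, 85]
  monthly_prob: [0.0004, 0.0007, 0.0010, 0.0017, 0.0026, 0.0054]
cpi:
  years:       [2015, 2016, 2017, 2018, 2019, 2020, 2021]
  multipliers: [1.027, 1.038, 1.06, 1.043, 1.024, 1.018, 1.004]
  exchange_rate_cny_per_usd: 6.4515
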