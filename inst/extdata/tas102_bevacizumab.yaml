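# Bundled scenario: TAS-102 + bevacizumab combination therapy versus
# TAS-102 monotherapy in chemorefractory metastatic colorectal cancer,
# Japanese health-care payer perspective (costs in 2019 USD at 110.05
# JPY/USD).  Transition probabilities are per 8-week cycle; utilities are
# annual weights; min/max are the +/-25% deterministic sensitivity bounds.
model:
  cycle_length_weeks: 8.0
  n_cycles: 30
  annual_discount: 0.035
  wtp_threshold: 117746.0
  counting: cycle_start
  discounting: annualized
  reference: monotherapy
arms:
  monotherapy:
    transitions:
      progression: {base: 0.55459395, min: 0.41594546, max: 0.69324243, dist: beta_like}
      death: {base: 0.26230083, min: 0.19672562, max: 0.32787604, dist: beta_like}
      complication: {base: 0.1126958, min: 0.08452185, max: 0.14086975, dist: beta_like}
    utilities:
      stable: {base: 0.73, min: 0.5475, max: 0.9125, dist: beta_like}
      complication: {base: 0.73, min: 0.5475, max: 0.9125, dist: beta_like}
      progression: {base: 0.59, min: 0.4425, max: 0.7375, dist: beta_like}
      prog_complication: {base: 0.59, min: 0.4425, max: 0.7375, dist: beta_like}
      death: {base: 0.0, min: 0.0, max: 0.0, dist: beta_like}
    multiplicities:
      tas102: 2
      admin_fee_monotherapy: 2
    complication_cost: complication_monotherapy
  combination:
    transitions:
      progression: {base: 0.38191794, min: 0.28643845, max: 0.47739742, dist: beta_like}
      death: {base: 0.18161864, min: 0.13621398, max: 0.2270233, dist: beta_like}
      complication: {base: 0.0846049, min: 0.06345368, max: 0.10575613, dist: beta_like}
    utilities:
      stable: {base: 0.72, min: 0.54, max: 0.9, dist: beta_like}
      complication: {base: 0.72, min: 0.54, max: 0.9, dist: beta_like}
      progression: {base: 0.59, min: 0.4425, max: 0.7375, dist: beta_like}
      prog_complication: {base: 0.59, min: 0.4425, max: 0.7375, dist: beta_like}
      death: {base: 0.0, min: 0.0, max: 0.0, dist: beta_like}
    multiplicities:
      tas102: 2
      bevacizumab: 4
      admin_fee_combination: 2
    complication_cost: complication_combination
cost_items:
  tas102: {base: 1833.66516, min: 1375.24887, max: 2292.08145, dist: gamma_like}
  bevacizumab: {base: 767.945701, min: 575.959276, max: 959.932127, dist: gamma_like}
  iv_drip_fee: {base: 65.6108597, min: 49.2081448, max: 82.0135747, dist: gamma_like}
  chemo_admin_fee: {base: 36.199095, min: 27.1493213, max: 45.2488688, dist: gamma_like}
  outpatient_service_fee: {base: 6.60633484, min: 4.95475113, max: 8.25791855, dist: gamma_like}
  prescription_fee: {base: 3.80090498, min: 2.85067873, max: 4.75113122, dist: gamma_like}
  admin_fee_monotherapy: {base: 10.4072398, min: 7.80542986, max: 13.0090498, dist: gamma_like}
  admin_fee_combination: {base: 220.633484, min: 165.475113, max: 275.791855, dist: gamma_like}
  complication_monotherapy: {base: 28.7519014, min: 21.5639261, max: 35.9398768, dist: gamma_like}
  complication_combination: {base: 72.0921038, min: 54.0690778, max: 90.1151297, dist: gamma_like}
metadata:
  currency: USD
  exchange_rate_jpy_per_usd: 110.05
  body_weight_kg: 65.0
  body_surface_area_m2: 1.72
  wtp_note: "threefold 2018 per-capita GDP of Japan; an alternative figure of
    $117,912/QALY also circulates for the same threshold"
  psa_default_seed: 20210420
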