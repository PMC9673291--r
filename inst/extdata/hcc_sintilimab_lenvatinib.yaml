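# Model configuration: first-line sintilimab + bevacizumab biosimilar vs
# lenvatinib for unresectable/metastatic hepatocellular carcinoma, Chinese
# healthcare system perspective, 2021 USD (1 USD = 6.47 RMB, metadata only).
#
# The survival calibration block is SYNTHETIC: the trial's patient-level
# data are not deposited, so the generator draws pseudo-IPD from log-normal
# distributions. The PFS median (4.6 months) matches the published trial
# summary; the log-scale spread of both endpoints and the OS median (the
# trial reports the OS median as not reached) are declared calibration
# assumptions, not published values.

metadata:
  currency: 2021 USD
  usd_to_rmb: 6.47
  description: >
    Three-state partitioned survival model, 3-week cycle, lifetime horizon,
    5%/year discounting.

settings:
  cycle_weeks: 3
  horizon_cycles: 522          # 30 years of 3-week cycles
  annual_discount: 0.05
  body_weight_kg: 65
  bevacizumab_mg_per_kg: 15
  scenario_bevacizumab_mg_per_kg: 7.5
  ae_window_cycles: 17.38095   # 365/21: adverse events occur in the first year
  half_cycle_correction: false
  wtp_thresholds: [12516.0, 37547.0]   # 1x and 3x GDP per capita, China 2021
  seed: 20210647
  psa_iterations: 5000

strategies:
  intervention: sintilimab_bevacizumab
  comparator: lenvatinib

survival:
  source: simulate
  n_patients: 380
  accrual_months: 12
  followup_months: 30
  calibration:
    pfs: {family: lognormal, median_months: 4.6, sdlog: 1.0}
    os: {family: lognormal, median_months: 18.0, sdlog: 1.1}
  ipd_paths:
    pfs: ~
    os: ~

# Intervention vs comparator (indirect comparison through the common
# sorafenib arm of the two source trials).
hazard_ratios:
  pfs: {hr: 0.856, ci_low: 0.798, ci_high: 0.910}
  os: {hr: 0.618, ci_low: 0.546, ci_high: 0.708}

# Published per-trial effects vs the common anchor, used by the
# indirect-comparison cross-check. The intervention's OS effect vs the
# anchor is not published (median not reached), so the OS contrast cannot
# be re-derived here.
anchored_trial_effects:
  - {trial_id: ORIENT-32, arm_a: sintilimab_bevacizumab, arm_b: sorafenib,
     endpoint: PFS, hr: 0.56}
  - {trial_id: REFLECT, arm_a: lenvatinib, arm_b: sorafenib,
     endpoint: PFS, hr: 0.66}
  - {trial_id: REFLECT, arm_a: lenvatinib, arm_b: sorafenib,
     endpoint: OS, hr: 0.92}

drug_prices:
  sintilimab_100mg: {base: 166.92, low: 133.54, high: 166.92}
  bevacizumab_100mg: {base: 177.13, low: 123.99, high: 177.13}
  lenvatinib_4mg: {base: 16.69, low: 11.68, high: 16.69}

regimens:
  sintilimab_bevacizumab:
    - {name: sintilimab, type: flat_iv, dose_mg: 200, vial_mg: 100,
       price: sintilimab_100mg}
    - {name: bevacizumab_biosimilar, type: weight_iv,
       mg_per_kg: from_settings, vial_mg: 100, price: bevacizumab_100mg}
  lenvatinib:
    - {name: lenvatinib, type: oral_daily, daily_mg: 12, unit_mg: 4,
       days_per_cycle: 21, price: lenvatinib_4mg}

subsequent_costs:   # per cycle, post-progression state
  sintilimab_bevacizumab: {base: 442.29, low: 353.83, high: 530.74}
  lenvatinib: {base: 631.81, low: 505.45, high: 758.17}

end_of_life_cost: {base: 2132.67, low: 888.10, high: 6108.44}

followup_costs:   # per visit, one visit per cycle for alive patients
  computed_tomography: {base: 90.43, low: 64.91, high: 146.83}
  blood_biochemistry: {base: 24.27, low: 13.76, high: 38.02}
  blood_routine: {base: 1.58, low: 0.77, high: 2.94}
  urine_routine: {base: 0.67, low: 0.15, high: 1.39}
  myocardial_enzyme: {base: 5.13, low: 3.09, high: 7.73}
  alpha_fetoprotein: {base: 3.18, low: 2.16, high: 4.64}

admin_costs:
  diagnosis: {base: 5.13, low: 3.09, high: 7.73}
  intravenous_injection: {base: 1.73, low: 0.46, high: 4.64}
  nursing: {base: 1.27, low: 0.77, high: 1.85}
  bed: {base: 2.05, low: 1.64, high: 2.47}

admin_components:
  sintilimab_bevacizumab: [diagnosis, intravenous_injection, nursing, bed]
  lenvatinib: [diagnosis]

ae_costs:   # per event, grade >= 3 events with incidence >= 5%
  hypertension: {base: 3.42, low: 2.73, high: 4.10}
  proteinuria: {base: 22.10, low: 17.68, high: 26.52}
  platelet_count_decreased: {base: 176.55, low: 141.24, high: 211.86}
  elevated_bilirubin: {base: 77.28, low: 61.82, high: 92.74}
  elevated_ast: {base: 77.28, low: 61.82, high: 92.74}

ae_disutilities:
  hypertension: {base: -0.12, low: -0.14, high: -0.10}
  proteinuria: {base: -0.12, low: -0.14, high: -0.10}
  platelet_count_decreased: {base: 0.0, low: 0.0, high: 0.0}
  elevated_bilirubin: {base: 0.0, low: 0.0, high: 0.0}
  elevated_ast: {base: 0.0, low: 0.0, high: 0.0}

ae_probabilities:   # per 3-week cycle, first year only
  sintilimab_bevacizumab:
    hypertension: {base: 0.0072, low: 0.0058, high: 0.0087}
    platelet_count_decreased: {base: 0.0033, low: 0.0027, high: 0.0040}
  lenvatinib:
    hypertension: {base: 0.0132, low: 0.0106, high: 0.0158}
    proteinuria: {base: 0.0035, low: 0.0028, high: 0.0041}
    platelet_count_decreased: {base: 0.0029, low: 0.0023, high: 0.0035}
    elevated_bilirubin: {base: 0.0040, low: 0.0032, high: 0.0048}
    elevated_ast: {base: 0.0029, low: 0.0023, high: 0.0035}

utilities:
  pfs: {base: 0.745, low: 0.730, high: 0.760}
  pp: {base: 0.678, low: 0.655, high: 0.701}

# Per-cycle discount rate is derived from the annual rate; the range below
# drives the sensitivity analyses.
discount_per_cycle: {low: 0.0, high: 0.0044}

treatment_cap_cycles:
  sintilimab_bevacizumab: 35   # 2 years of 3-week cycles
  lenvatinib: none             # treat until progression
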