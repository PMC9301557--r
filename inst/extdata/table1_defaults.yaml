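# Packaged base-case inputs for the LDCT screening state-transition model.
# Percent-style entries carry an explicit units key; everything else is a
# proportion, an annual probability, a rate per 100,000 person-years, or CNY.
incidence_per_100k:
  - {age_lower: 50, age_upper: 54, male: 81.0559, female: 89.6626}
  - {age_lower: 55, age_upper: 59, male: 162.0833, female: 112.4574}
  - {age_lower: 60, age_upper: 64, male: 256.0943, female: 154.6871}
  - {age_lower: 65, age_upper: 69, male: 373.6808, female: 190.2521}
  - {age_lower: 70, age_upper: 74, male: 498.0681, female: 242.6310}
smoking_rate:
  - {age_lower: 50, age_upper: 64, male: 0.60, female: 0.04}
  - {age_lower: 65, age_upper: 74, male: 0.45, female: 0.07}
risk:
  # the smoker odds ratio is not reported alongside the base inputs;
  # 2.5 is an assumed default and is flagged as such downstream
  odds_ratio_smoker: 2.5
  odds_ratio_assumed: true
  rr_heavy: 3.87
stage_distribution:
  nonscreened: {CIS: 0.000, I: 0.190, II: 0.165, III: 0.346, IV: 0.299}
  screened: {CIS: 0.0370, I: 0.6852, II: 0.0370, III: 0.1852, IV: 0.0556}
ldct:
  sensitivity: {value: 79, units: percent}
  specificity: {value: 81, units: percent}
mortality:
  all_cause:
    - {age_lower: 50, age_upper: 54, value: 3.59, units: percent}
    - {age_lower: 55, age_upper: 59, value: 4.73, units: percent}
    - {age_lower: 60, age_upper: 64, value: 8.19, units: percent}
    - {age_lower: 65, age_upper: 69, value: 12.99, units: percent}
    - {age_lower: 70, age_upper: 74, value: 21.08, units: percent}
  lung_cancer_per_100k:
    - {age_lower: 50, age_upper: 54, value: 28.81}
    - {age_lower: 55, age_upper: 59, value: 52.86}
    - {age_lower: 60, age_upper: 64, value: 101.93}
    - {age_lower: 65, age_upper: 69, value: 153.34}
    - {age_lower: 70, age_upper: 74, value: 248.57}
transitions:
  progression:
    cis_to_I: 0.0980
    I_to_II: 0.3682
    I_to_III: 0.0328
    I_to_IV: 0.0745
    II_to_III: 0.2260
    II_to_IV: 0.1510
    III_to_IV: 0.1455
  lc_death: {CIS: 0.00, I: 0.04, II: 0.07, III: 0.13, IV: 0.18}
utilities: {Healthy: 1.0, CIS: 0.87, I: 0.84, II: 0.84, III: 0.87, IV: 0.75}
costs:
  direct_screening: 245.86
  indirect_screening: 23.07
  prediagnosis: 628.36
  biopsy: 1232.44
  treatment:
    CIS: 47341.85
    I: 53344.51
    II: 83365.95
    III: 90643.18
    IV: 116471.34
  maintenance_fraction: 0.10
  cpi_rate: 0.0
economics:
  discount_rate: 0.05
  threshold: 212676
  horizon_end_age: 79
  cohort_size: 100000
  cycle_length: 1
psa:
  cv: 0.1
options:
  all_cause_interpretation: five_year
  rate_conversion: exponential
  heavy_incidence_mode: as_printed
  sex_mix: ~
  diagnosed_progression: none
  undiagnosed_utility: stage
  screen_stage_split: never
  band_extrapolation: carry_forward
  incidence_multiplier: 1.0
  half_cycle_correction: false
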