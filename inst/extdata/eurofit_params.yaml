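# Model input parameters for the EuroFIT cost-effectiveness model.
#
# Units: probabilities are annual transition probabilities (per 1-year
# cycle); utilities are QALY weights per person-year; costs are euro
# (price year 2017) per person-year; program_cost is euro per participant,
# one-off at enrolment; discount rates are annual.
#
# Each sampled parameter carries the published two-figure point value
# ("printed") and its PSA distribution. For the activity transitions the
# beta parameters encode the unrounded trial proportions (each row of
# beta means sums to ~1); the deterministic engine therefore uses the
# beta mean as the working value and keeps "printed" for display and
# audit. Literature-sourced parameters are fixed and never sampled.
model:
  cohort_size: 10000
  horizon_years: 5
  cycle_length_years: 1
  discount_rate_costs: 0.035
  discount_rate_effects: 0.035
  effect_duration_years: horizon
  initial_activity:
    inactive: 0.175
    moderate: 0.105
    recommended: 0.720
analysis:
  perspective: societal
  utility_source: trial
activity_transitions:
  eurofit:
    - {from: inactive, to: inactive, printed: 0.18, dist: beta, alpha: 4.0, beta: 17.0}
    - {from: inactive, to: moderate, printed: 0.054, dist: beta, alpha: 0.34, beta: 5.7}
    - {from: inactive, to: recommended, printed: 0.71, dist: beta, alpha: 59.4, beta: 19.6}
    - {from: moderate, to: inactive, printed: 0.085, dist: beta, alpha: 0.44, beta: 4.56}
    - {from: moderate, to: moderate, printed: 0.042, dist: beta, alpha: 0.09, beta: 1.9}
    - {from: moderate, to: recommended, printed: 0.82, dist: beta, alpha: 33.8, beta: 5.2}
    - {from: recommended, to: inactive, printed: 0.042, dist: beta, alpha: 0.83, beta: 18.2}
    - {from: recommended, to: moderate, printed: 0.023, dist: beta, alpha: 0.24, beta: 9.8}
    - {from: recommended, to: recommended, printed: 0.89, dist: beta, alpha: 357.9, beta: 26.1}
  control:
    - {from: inactive, to: inactive, printed: 0.33, dist: beta, alpha: 11.5, beta: 21.5}
    - {from: inactive, to: moderate, printed: 0.12, dist: beta, alpha: 1.6, beta: 10.4}
    - {from: inactive, to: recommended, printed: 0.49, dist: beta, alpha: 25.0, beta: 23.0}
    - {from: moderate, to: inactive, printed: 0.19, dist: beta, alpha: 2.1, beta: 8.0}
    - {from: moderate, to: moderate, printed: 0.17, dist: beta, alpha: 1.5, beta: 6.6}
    - {from: moderate, to: recommended, printed: 0.58, dist: beta, alpha: 16.6, beta: 10.4}
    - {from: recommended, to: inactive, printed: 0.10, dist: beta, alpha: 4.2, beta: 37.8}
    - {from: recommended, to: moderate, printed: 0.064, dist: beta, alpha: 1.9, beta: 26.1}
    - {from: recommended, to: recommended, printed: 0.80, dist: beta, alpha: 290.7, beta: 58.3}
disease_incidence:
  inactive:
    colorectal_cancer: 0.015
    chd: 0.011
    t2d: 0.005
    stroke: 0.0046
    depression: 0.010
  moderate:
    colorectal_cancer: 0.011
    chd: 0.009
    t2d: 0.0038
    stroke: 0.0033
    depression: 0.0094
  recommended:
    colorectal_cancer: 0.0096
    chd: 0.008
    t2d: 0.0033
    stroke: 0.0029
    depression: 0.0092
activity_mortality:
  inactive: 0.016
  moderate: 0.012
  recommended: 0.010
disease_mortality:
  colorectal_cancer: 0.092
  chd: 0.002
  t2d: 0.015
  stroke: 0.400
  depression: 0.030
utilities:
  trial:
    - {state: inactive, printed: 0.909, dist: beta, alpha: 3.0, beta: 0.38}
    - {state: moderate, printed: 0.919, dist: beta, alpha: 5.1, beta: 0.51}
    - {state: recommended, printed: 0.922, dist: beta, alpha: 5.1, beta: 0.43}
  literature:
    - {state: inactive, printed: 0.80, dist: fixed}
    - {state: moderate, printed: 0.87, dist: fixed}
    - {state: recommended, printed: 0.91, dist: fixed}
  condition:
    - {state: colorectal_cancer, printed: 0.786, dist: fixed}
    - {state: chd, printed: 0.735, dist: fixed}
    - {state: t2d, printed: 0.785, dist: fixed}
    - {state: stroke, printed: 0.62, dist: fixed}
    - {state: depression, printed: 0.57, dist: fixed}
annual_costs:
  societal:
    - {state: inactive, printed: 2436, dist: gamma, shape: 0.19, scale: 12658}
    - {state: moderate, printed: 1506, dist: gamma, shape: 0.22, scale: 6920}
    - {state: recommended, printed: 1997, dist: gamma, shape: 0.24, scale: 8222}
    - {state: colorectal_cancer, printed: 34085, dist: fixed}
    - {state: chd, printed: 5239, dist: fixed}
    - {state: t2d, printed: 5907, dist: fixed}
    - {state: stroke, printed: 24979, dist: fixed}
    - {state: depression, printed: 6819, dist: fixed}
  healthcare:
    - {state: inactive, printed: 1107, dist: gamma, shape: 0.10, scale: 10924}
    - {state: moderate, printed: 594, dist: gamma, shape: 0.35, scale: 1707}
    - {state: recommended, printed: 747, dist: gamma, shape: 0.19, scale: 4040}
    - {state: colorectal_cancer, printed: 25346, dist: fixed}
    - {state: chd, printed: 1954, dist: fixed}
    - {state: t2d, printed: 3089, dist: fixed}
    - {state: stroke, printed: 18750, dist: fixed}
    - {state: depression, printed: 966, dist: fixed}
program_cost: 260
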