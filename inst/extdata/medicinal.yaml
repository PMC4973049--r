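---
schema: 1
variant: medicinal
description: Safe storage of medicines (ICD-10 X40-X44)
probabilities:
  pSafe:
    family: beta
    counts: {successes: 1527, total: 2033}
    citation: community controls with safe storage of medicines, UK case-control study
  pAccept:
    family: fixed
    value: 0.90
    citation: assumed uptake, identical across interventions
  orIngest:
    family: normal
    log_or: -0.604
    se: 0.143
    citation: >
      case-control adjusted odds ratio for ingestion, safe vs no safe
      storage; reported OR 1.83 (95% CI 1.38-2.42), operative signed
      log-odds-ratio -0.604 (SE 0.143) as printed
  pAmb:
    family: fixed
    value: 0.242
    cost_weight: 0.24
    citation: proportion of cases arriving by emergency ambulance (HES 2012);
      unit-cost arithmetic uses the rounded weight 0.24
  incidence:
    per_10000: 30.1
    population: 3996400
    substance_share: 0.6
    england_admissions: 3909
    uk_scale: 1.163
    severe_rate: 0.0191
    severe_cases: 87
    fatal: {deaths: 1, denominator: 86}
    citation: UK incidence 30.1/10,000 person-years in under 5s; 60% of
      medically reported poisonings medicinal; HES admissions scaled
      England to UK
effectiveness:
  citation: network meta-analysis posterior summaries (median, 95% CrI) of
    the absolute probability of safe storage under each strategy
  arms:
    - {arm: 1, median: 0.87, lower: 0.56, upper: 0.98}
    - {arm: 2, median: 0.90, lower: 0.61, upper: 0.98}
    - {arm: 3, median: 0.93, lower: 0.65, upper: 0.99}
    - {arm: 4, median: 0.94, lower: 0.74, upper: 0.99}
    - {arm: 5, median: 0.90, lower: 0.56, upper: 0.99}
    - {arm: 6, median: 0.90, lower: 0.59, upper: 0.98}
    - {arm: 7, median: 0.93, lower: 0.66, upper: 0.99}
costs:
  currency: GBP 2012
  components: {education: 3.67, equipment: 7.45, inspection: 3.67,
               fitting: 2.08, travel: 4.99}
  cFixed: {family: fixed, value: 79529}
  cAccept: {family: fixed, value: 0.40}
  cAmb: {family: gamma, mean: 263, se: 21.48}
  cED1: {family: gamma, mean: 112, se: 27.41}
  cED2: {family: gamma, mean: 146, se: 42.22}
  cAdmit1: {family: gamma, mean: 586, se: 223.70}
  cAdmit2: {family: gamma, mean: 2461, se: 810.37}
  cChro: {family: gamma, mean: 386.42, se: 96.72}
  cFatal: {family: fixed, value: 205.50}
  cGP: {family: fixed, value: 43}
utilities:
  uPop:
    - {age_from: 0, age_to: 24, mean: 0.94, sd: 0.12}
    - {age_from: 25, age_to: 34, mean: 0.93, sd: 0.15}
    - {age_from: 35, age_to: 44, mean: 0.91, sd: 0.16}
    - {age_from: 45, age_to: 54, mean: 0.85, sd: 0.25}
    - {age_from: 55, age_to: 64, mean: 0.80, sd: 0.26}
    - {age_from: 65, age_to: 74, mean: 0.78, sd: 0.26}
    - {age_from: 75, age_to: 99, mean: 0.73, sd: 0.27}
  decrements:
    uMinor: {mean: 0.03, se: 0.003}
    uModerate: {mean: 0.046, se: 0.0046}
    uSevere: {mean: 0.146, se: 0.0146}
    uChronic: {mean: 0.10, se: 0.025}
settings:
  cohort_size: 100000
  reporting_scale: 1000
  cycle_length: 1
  horizon: 100
  preschool_years: 5
  discount_costs: 0.035
  discount_utilities: 0.035
  half_cycle_correction: no
  children_per_household: 1.0
  costing_policy: target-unsafe
  rho: 0.9
  predictive_inflation: 1.5
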