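# Default model parameters: means, 95% CIs and PSA distribution families for
# the falls-prevention cost-utility model (2019 AUD). Probability rows for the
# fall event tree are conditional branch probabilities; the exercise-arm
# relative risks are marginal annual effects.

# --- transition probabilities (annual / conditional on a fall) ---
p_fall_year1:
  mean: 0.36
  ci_low: 0.29
  ci_high: 0.43
  family: beta
  units: annual probability
  source: falls and frailty cohort, ADT users
p_fall_recurrent:
  mean: 0.65
  ci_low: 0.53
  ci_high: 0.77
  family: beta
  units: annual probability
  source: falls and frailty cohort, ADT users
rr_fall_exercise:
  mean: 0.76
  ci_low: 0.70
  ci_high: 0.81
  family: lognormal
  units: relative risk
  source: meta-analysis, exercise for falls prevention
p_fracture:
  mean: 0.12
  ci_low: 0.09
  ci_high: 0.15
  family: beta
  units: probability per fall
  source: meta-analysis, fall-related fractures
rr_fracture_exercise:
  mean: 0.44
  ci_low: 0.25
  ci_high: 0.76
  family: lognormal
  units: relative risk
  source: meta-analysis, fall-related fractures
p_fx_major:
  mean: 0.62
  ci_low: 0.58
  ci_high: 0.66
  family: beta
  units: proportion of fractures
  source: population cohort, ADT users
p_fx_minor:
  mean: 0.38
  ci_low: 0.34
  ci_high: 0.42
  family: complement
  units: proportion of fractures
  source: population cohort, ADT users
p_nonfx_injury:
  mean: 0.88
  ci_low: 0.87
  ci_high: 0.89
  family: beta
  units: probability per non-fracture fall
  source: meta-analysis, fall injuries
rr_injury_exercise:
  mean: 0.70
  ci_low: 0.54
  ci_high: 0.92
  family: lognormal
  units: relative risk
  source: meta-analysis, fall injuries
p_inj_major:
  mean: 0.06
  ci_low: 0.055
  ci_high: 0.065
  family: beta
  units: proportion of non-fracture injuries
  source: population cohort, ADT users
p_inj_minor:
  mean: 0.94
  ci_low: 0.93
  ci_high: 0.95
  family: complement
  units: proportion of non-fracture injuries
  source: population cohort, ADT users
p_death_fall_60_64:
  mean: 0.023
  ci_low: 0.015
  ci_high: 0.031
  family: beta
  units: probability of death given a major fall event, ages 60-64
  source: falls mortality study
p_death_fall_65_69:
  mean: 0.043
  ci_low: 0.033
  ci_high: 0.053
  family: beta
  units: probability of death given a major fall event, ages 65-69
  source: falls mortality study
p_death_fall_70_74:
  mean: 0.065
  ci_low: 0.062
  ci_high: 0.068
  family: beta
  units: probability of death given a major fall event, ages 70-74
  source: falls mortality study

# --- one-off treatment costs (2019 AUD) ---
c_fx_major:
  mean: 20724
  ci_low: 20082
  ci_high: 21366
  family: gamma
  units: AUD
  source: fracture costing study, indexed to 2019
c_fx_minor:
  mean: 8797
  ci_low: 8524
  ci_high: 9070
  family: gamma
  units: AUD
  source: fracture costing study, indexed to 2019
c_inj_major:
  mean: 10040
  ci_low: 9729
  ci_high: 10351
  family: gamma
  units: AUD
  source: hospital pricing and community care costs
c_inj_minor:
  mean: 1115
  ci_low: 1080
  ci_high: 1150
  family: gamma
  units: AUD
  source: hospital pricing and community care costs
c_intervention:
  mean: 767
  ci_low: 743
  ci_high: 791
  family: gamma
  units: AUD per participant
  source: MBS-valued supervised exercise programme

# --- health state utilities ---
u_baseline:
  mean: 0.79
  ci_low: 0.78
  ci_high: 0.80
  family: beta
  units: utility
  source: PORPUS-U, men on radiation therapy + ADT
u_fx_major:
  mean: 0.475
  ci_low: 0.47
  ci_high: 0.49
  family: beta
  units: utility
  source: osteoporotic fracture utility study
u_fx_minor:
  mean: 0.565
  ci_low: 0.55
  ci_high: 0.59
  family: beta
  units: utility
  source: osteoporotic fracture utility study
u_inj_major:
  mean: 0.47
  ci_low: 0.46
  ci_high: 0.48
  family: beta
  units: utility
  source: traumatic brain injury decrement
u_inj_minor:
  mean: 0.765
  ci_low: 0.76
  ci_high: 0.80
  family: beta
  units: utility
  source: community falls quality-of-life study
u_recurrent_control:
  mean: 0.72
  ci_low: 0.70
  ci_high: 0.74
  family: beta
  units: utility
  source: community falls quality-of-life study
u_recurrent_exercise:
  mean: 0.74
  ci_low: 0.72
  ci_high: 0.76
  family: beta
  units: utility
  source: meta-analysis, exercise and fear of falling

# --- structural constants (not sampled in PSA) ---
start_age:
  mean: 68
  family: fixed
  units: years
effect_years:
  mean: 3
  family: fixed
  units: years of sustained exercise effect (1-year programme + 2 years)
horizon_years:
  mean: 3
  family: fixed
  units: years
cycle_months:
  mean: 3
  family: fixed
  units: months
discount_annual:
  mean: 0.05
  family: fixed
  units: annual rate
wtp:
  mean: 50000
  family: fixed
  units: AUD per QALY
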