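# Boost-phase clinical objectives (all doses in Gy).
# Boost: 30 Gy in 5 fractions prescribed at the 90% CTV coverage level.
# Cumulative limits are EQD2 including the prior uniform EBRT course.
boost_fractions: 5
prior:
  total_gy: 45.0
  fractions: 25
ctv:
  d90_gy: 30.0
  v45_aim_pct: 50.0
  v60_aim_pct: 30.0
  alpha_beta: 10.0
oars:
  - structure: bladder
    aim_gy: 23.75
    hard_gy: 27.5
    cumulative_gy: 80.0
    alpha_beta: 3.0
  - structure: rectum
    aim_gy: 17.0
    hard_gy: 19.45
    cumulative_gy: 65.0
    alpha_beta: 3.0
  - structure: sigmoid
    aim_gy: 19.5
    hard_gy: 21.65
    cumulative_gy: 70.0
    alpha_beta: 3.0
  - structure: bowel
    aim_gy: 17.0
    hard_gy: 19.45
    cumulative_gy: 65.0
    alpha_beta: 3.0
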