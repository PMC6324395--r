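schema_version: 1
params:
  fatality_rate_child: 3.25e-06
  fatality_rate_adult: 1.81e-06
  rr_no_epi: 10.0
  p_reaction: 0.07
  p_ed_visit: 0.01
  p_carry: 0.67
  p_hospitalization: 0.35
  p_resolution: 0.22
  resolution_age: 4.0
  price_twin_pack: 715.0
  cost_hospitalization: 5899.0
  cost_ed: 691.0
  twin_packs_child: 2.0
  twin_packs_adult: 1.0
  adult_age_packs: 19.0
  adult_age_fatality: 20.0
  start_age: 0.0
  horizon: 80.0
  cycle_length: 1.0
  discount_rate: 0.03
  utility_decrement: 0.09
scenarios:
- name: base_case
- name: rr100
  overrides:
    rr_no_epi: 100.0
- name: perfect_carriage
  overrides:
    p_carry: 1.0
- name: rr100_perfect_carriage
  overrides:
    rr_no_epi: 100.0
    p_carry: 1.0
- name: hosp_doubled
  arm_overrides:
    not_prescribed:
      p_hospitalization: 0.7
- name: fatality_x10
  overrides:
    fatality_rate_child: 3.25e-05
    fatality_rate_adult: 1.81e-05
- name: fatality_x10_perfect_carriage
  overrides:
    fatality_rate_child: 3.25e-05
    fatality_rate_adult: 1.81e-05
    p_carry: 1.0
- name: rr100_fatality_x10
  overrides:
    rr_no_epi: 100.0
    fatality_rate_child: 3.25e-05
    fatality_rate_adult: 1.81e-05

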