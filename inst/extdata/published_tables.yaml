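economic:
  discount_rate_annual: 0.03
  cycle_length: 1.0
  start_age: 1.0
  horizon_end_age: 84.0
  currency_label: USD
  sgd_per_usd: 1.317
  half_cycle_on_qalys_only: yes
clinical:
  p_major_first_year: 0.01
  p_major_subsequent: 0.001
  p_wound_first_year: 0.005
  p_wound_subsequent: 0.0005
  p_explant_first_year: 0.005
  p_explant_subsequent: 0.0005
  max_internal_replacements: 2.0
  warranty_years: 10.0
  first_implant_complications_in_sequential: no
utilities:
  base_increment_bimodal: 0.232
  base_increment_bilateral_extra: 0.03
  printed_basis_bimodal: 0.232
  printed_basis_bilateral: 0.03
  age_bands:
  - age_low: 1.0
    age_high: 1.0
    scaling: 0.28
    printed_bimodal: 0.066
    printed_bilateral: 0.009
  - age_low: 2.0
    age_high: 3.0
    scaling: 0.91
    printed_bimodal: 0.212
    printed_bilateral: 0.027
  - age_low: 4.0
    age_high: 54.0
    scaling: 1.0
    printed_bimodal: 0.232
    printed_bilateral: 0.03
  - age_low: 55.0
    age_high: 64.0
    scaling: 0.98
    printed_bimodal: 0.227
    printed_bilateral: 0.0294
  - age_low: 65.0
    age_high: 69.0
    scaling: 0.96
    printed_bimodal: 0.223
    printed_bilateral: 0.0288
  - age_low: 70.0
    age_high: 74.0
    scaling: 0.91
    printed_bimodal: 0.211
    printed_bilateral: 0.0273
  - age_low: 75.0
    age_high: 79.0
    scaling: 0.84
    printed_bimodal: 0.195
    printed_bilateral: 0.0252
  - age_low: 80.0
    age_high: 84.0
    scaling: 0.72
    printed_bimodal: 0.167
    printed_bilateral: 0.0216
costs:
  surgery_implantation: 4940.0
  surgery_wound_revision: 6454.0
  surgery_explant_reimplant: 7115.0
  ward_day: 172.0
  ci_device: 28216.0
  hearing_aid: 949.0
  aided_hearing_test: 29.0
  audiologist_session: 81.0
  auditory_assessment: 53.0
  avt_slp_session: 116.0
  ct_scan: 405.0
  ent_review: 57.0
  speech_assessment: 35.0
  external_processor_replacement: 5923.03
  external_processor_cycle_years: 7.0
  hearing_aid_cycle_years: 5.0
  initial_implant_cost_multiplier: 1.0
strategies:
  BIMODAL:
    arm: BIMODAL
    age_first_implant: 1.0
    replacement_cost_multiplier: 1.0
  SIMULTANEOUS:
    arm: SIMULTANEOUS
    age_first_implant: 1.0
    age_second_implant: 1.0
    replacement_cost_multiplier: 2.0
  SEQUENTIAL:
    arm: SEQUENTIAL
    age_first_implant: 1.0
    age_second_implant: 3.0
    replacement_cost_multiplier: 2.0
resource_schedule:
  scheduled:
  - arm: ALL
    model_year: 1.0
    resource: ci_device
    units: 1.0
    category: acquisition
  - arm: ALL
    model_year: 1.0
    resource: surgery_implantation
    units: 1.0
    category: acquisition
  - arm: ALL
    model_year: 1.0
    resource: ward_day
    units: 1.0
    category: acquisition
  - arm: ALL
    model_year: 1.0
    resource: audiologist_session
    units: 10.0
    category: habilitation
  - arm: ALL
    model_year: 1.0
    resource: auditory_assessment
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 1.0
    resource: avt_slp_session
    units: 52.0
    category: habilitation
  - arm: ALL
    model_year: 1.0
    resource: ent_review
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 1.0
    resource: speech_assessment
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 2.0
    resource: audiologist_session
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 2.0
    resource: auditory_assessment
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 2.0
    resource: avt_slp_session
    units: 26.0
    category: habilitation
  - arm: ALL
    model_year: 2.0
    resource: ent_review
    units: 1.0
    category: habilitation
  - arm: ALL
    model_year: 2.0
    resource: speech_assessment
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 3.0
    resource: audiologist_session
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 3.0
    resource: auditory_assessment
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 3.0
    resource: avt_slp_session
    units: 2.0
    category: habilitation
  - arm: ALL
    model_year: 3.0
    resource: ent_review
    units: 1.0
    category: habilitation
  - arm: ALL
    model_year: 3.0
    resource: speech_assessment
    units: 2.0
    category: habilitation
  - arm: SIMULTANEOUS
    model_year: 1.0
    resource: ci_device
    units: 1.0
    category: acquisition
  - arm: SIMULTANEOUS
    model_year: 1.0
    resource: surgery_implantation
    units: 1.0
    category: acquisition
  - arm: SEQUENTIAL
    model_year: 2.0
    resource: audiologist_session
    units: 4.0
    category: presurgery
  - arm: SEQUENTIAL
    model_year: 2.0
    resource: auditory_assessment
    units: 4.0
    category: presurgery
  - arm: SEQUENTIAL
    model_year: 2.0
    resource: avt_slp_session
    units: 6.0
    category: presurgery
  - arm: SEQUENTIAL
    model_year: 2.0
    resource: ent_review
    units: 2.0
    category: presurgery
  - arm: SEQUENTIAL
    model_year: 2.0
    resource: speech_assessment
    units: 1.0
    category: presurgery
  - arm: SEQUENTIAL
    model_year: 2.0
    resource: ct_scan
    units: 1.0
    category: presurgery
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: ci_device
    units: 1.0
    category: acquisition
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: surgery_implantation
    units: 1.0
    category: acquisition
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: ward_day
    units: 1.0
    category: acquisition
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: audiologist_session
    units: 10.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: auditory_assessment
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: avt_slp_session
    units: 52.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: ent_review
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 3.0
    resource: speech_assessment
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 4.0
    resource: audiologist_session
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 4.0
    resource: auditory_assessment
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 4.0
    resource: avt_slp_session
    units: 26.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 4.0
    resource: ent_review
    units: 1.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 4.0
    resource: speech_assessment
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 5.0
    resource: audiologist_session
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 5.0
    resource: auditory_assessment
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 5.0
    resource: avt_slp_session
    units: 2.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 5.0
    resource: ent_review
    units: 1.0
    category: habilitation
  - arm: SEQUENTIAL
    model_year: 5.0
    resource: speech_assessment
    units: 2.0
    category: habilitation
  periodic:
  - arm: ALL
    resource: external_processor_replacement
    units: 1.0
    cycle_years: 7.0
    anchor_year: 1.0
  - arm: SIMULTANEOUS
    resource: external_processor_replacement
    units: 1.0
    cycle_years: 7.0
    anchor_year: 1.0
  - arm: SEQUENTIAL
    resource: external_processor_replacement
    units: 1.0
    cycle_years: 7.0
    anchor_year: 3.0
  - arm: BIMODAL
    resource: hearing_aid
    units: 1.0
    cycle_years: 5.0
    anchor_year: 0.0
reliability:
  intercept: 0.998749
  slope_per_year: 0.002911
  valid_from_year: 20.0
  valid_to_year: 80.0
  floor: 0.01
psa:
  cv_costs: 1.0
  cv_utilities: 1.0
life_table_ref: synthetic_sg_lifetable.csv

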