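# Parameter-file schema (YAML)
#
# All keys are optional unless marked REQUIRED; omitted keys take the
# package defaults (the published table values). Load with
# bicea::load_parameters(); unknown keys are an error.

economic:                      # mapping
  discount_rate_annual: float    # in [0, 1); default 0.03
  cycle_length: float            # years; fixed at 1
  start_age: int                 # default 1
  horizon_end_age: int           # default 84 (end of last utility band)
  currency_label: str            # default "USD"
  sgd_per_usd: float             # reporting only; default 1.317
  half_cycle_on_qalys_only: bool # default true

clinical:                      # annual probabilities, first year of each
                               # device vs subsequent years
  p_major_first_year: float      # default 0.01 (= wound + explant)
  p_major_subsequent: float      # default 0.001
  p_wound_first_year: float      # default 0.005
  p_wound_subsequent: float      # default 0.0005
  p_explant_first_year: float    # default 0.005
  p_explant_subsequent: float    # default 0.0005
  max_internal_replacements: int # default 2
  warranty_years: int            # default 10
  first_implant_complications_in_sequential: bool  # default false

utilities:
  base_increment_bimodal: float          # default 0.232 /yr
  base_increment_bilateral_extra: float  # default 0.03 /yr
  printed_basis_bimodal: float           # base the printed cells belong to
  printed_basis_bilateral: float
  age_bands:                   # ordered, contiguous bands
  - age_low: int
    age_high: int
    scaling: float             # in (0, 1]
    printed_bimodal: float     # literal table cell, used verbatim when the
    printed_bilateral: float   # base equals its printed basis

costs:                         # 2017 USD unit costs
  surgery_implantation: float            # default 4940
  surgery_wound_revision: float          # default 6454
  surgery_explant_reimplant: float       # default 7115
  ward_day: float                        # default 172
  ci_device: float                       # default 28216
  hearing_aid: float                     # default 949
  aided_hearing_test: float              # default 29
  audiologist_session: float             # default 81
  auditory_assessment: float             # default 53
  avt_slp_session: float                 # default 116
  ct_scan: float                         # default 405
  ent_review: float                      # default 57
  speech_assessment: float               # default 35
  external_processor_replacement: float  # REQUIRED -- no published value;
                                         # the packaged fixture carries a
                                         # calibrated reconstruction
  external_processor_cycle_years: int    # default 7
  hearing_aid_cycle_years: int           # default 5
  initial_implant_cost_multiplier: float # default 1; scales the initial
                                         # acquisition items of bilateral
                                         # arms (sensitivity-analysis knob)

strategies:                    # mapping keyed BIMODAL / SIMULTANEOUS /
                               # SEQUENTIAL
  SIMULTANEOUS:
    age_first_implant: int       # default 1
    age_second_implant: int      # 1 simultaneous, 3 sequential, absent bimodal
    replacement_cost_multiplier: float  # 2 bilateral, 1 bimodal

resource_schedule:             # optional; defaults to the published schedule
  scheduled:                   # list of rows
  - arm: str                     # BIMODAL/SIMULTANEOUS/SEQUENTIAL/ALL
                                 # (ALL = shared first-implant backbone)
    model_year: int
    resource: str                # a costs: field name
    units: float
    category: str                # acquisition | habilitation | presurgery
  periodic:                    # list of rows
  - arm: str
    resource: str
    units: float
    cycle_years: int
    anchor_year: int             # fires when (year - anchor) %% cycle == 0,
                                 # strictly after the anchor year

reliability:                   # linear cumulative-survival model
  intercept: float               # default 0.998749
  slope_per_year: float          # decline per year; default 0.002911
  valid_from_year: int           # default 20
  valid_to_year: int             # default 80
  floor: float                   # default 0.01

psa:
  cv_costs: float                # SD/mean for gamma cost draws; default 1.0
  cv_utilities: float            # SD/mean for beta utility draws; default 1.0

life_table_ref: str            # informational pointer to the life-table file
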