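# Default pipeline configuration.
# Drug map, regimen catalogue and comorbidity map are data, not code:
# new agents or site-specific code lists are added here, never in R/.

cohort:
  study_window_start: "2015-01-01"
  study_window_end: "2022-12-31"
  followup_min_months: 6
  lookback_record_years: 3
  sct_exclusion_start: "2008-04-01"
  baseline_months: 6
  index_drugs: [bortezomib, lenalidomide, daratumumab]
  mm_icd10_prefix: "C90"
  sct_procedure_codes: [SCT-AUTO]
  exclude_suspected: true
  month_granular_index: true

lines:
  formation_window_days: 56
  gap_threshold_days: 90
  injectable_coverage_days: 28
  novel_class_trigger: false
  conditioning_window_days: 14
  refill_gap_days: 30

eras:
  d_vmp_approval: "2019-08"
  drd_approval: "2019-12"

summary:
  percent_digits: 1
  era_percent_digits: 0
  months_divisor: 30.4375

drugs:
  - {name: lenalidomide,  class: IMiD,       abbreviation: R}
  - {name: pomalidomide,  class: IMiD,       abbreviation: P}
  - {name: thalidomide,   class: IMiD,       abbreviation: T}
  - {name: bortezomib,    class: PI,         abbreviation: V}
  - {name: carfilzomib,   class: PI,         abbreviation: K}
  - {name: ixazomib,      class: PI,         abbreviation: I}
  - {name: daratumumab,   class: anti-CD38,  abbreviation: D}
  - {name: isatuximab,    class: anti-CD38,  abbreviation: S}
  - {name: elotuzumab,    class: anti-SLAMF7, abbreviation: E}
  - {name: panobinostat,  class: HDACi,      abbreviation: F}
  - {name: melphalan,     class: alkylator,  abbreviation: M}
  - {name: dexamethasone, class: steroid,    abbreviation: d}
  - {name: prednisone,    class: steroid,    abbreviation: P}

# Exact-set regimen catalogue: a label matches only when the observed set of
# core drugs plus steroids equals the listed members exactly.
regimens:
  - {label: Bor-based,   members: [bortezomib]}
  - {label: Dara-based,  members: [daratumumab]}
  - {label: DKd-based,   members: [daratumumab, carfilzomib, dexamethasone]}
  - {label: DRd-based,   members: [daratumumab, lenalidomide, dexamethasone]}
  - {label: DVd-based,   members: [daratumumab, bortezomib, dexamethasone]}
  - {label: D-VMP-based, members: [daratumumab, bortezomib, melphalan, prednisone]}
  - {label: EPd-based,   members: [elotuzumab, pomalidomide, dexamethasone]}
  - {label: ERd-based,   members: [elotuzumab, lenalidomide, dexamethasone]}
  - {label: FVd-based,   members: [panobinostat, bortezomib, dexamethasone]}
  - {label: IRd-based,   members: [ixazomib, lenalidomide, dexamethasone]}
  - {label: Ixa-based,   members: [ixazomib]}
  - {label: Kd-based,    members: [carfilzomib, dexamethasone]}
  - {label: KRd-based,   members: [carfilzomib, lenalidomide, dexamethasone]}
  - {label: Len-based,   members: [lenalidomide]}
  - {label: Pd-based,    members: [pomalidomide, dexamethasone]}
  - {label: PVd-based,   members: [pomalidomide, bortezomib, dexamethasone]}
  - {label: Rd-based,    members: [lenalidomide, dexamethasone]}
  - {label: RVd-based,   members: [lenalidomide, bortezomib, dexamethasone]}
  - {label: Sar-based,   members: [isatuximab]}
  - {label: Sd-based,    members: [isatuximab, dexamethasone]}
  - {label: SPd-based,   members: [isatuximab, pomalidomide, dexamethasone]}
  - {label: Td-based,    members: [thalidomide, dexamethasone]}
  - {label: Vd-based,    members: [bortezomib, dexamethasone]}
  - {label: VMP-based,   members: [bortezomib, melphalan, prednisone]}
  # Quadruplet and later-line combinations observed in practice:
  - {label: D-RVd-based, members: [daratumumab, lenalidomide, bortezomib, dexamethasone]}
  - {label: SKd-based,   members: [isatuximab, carfilzomib, dexamethasone]}

# Baseline comorbidity categories as ICD-10 prefix lists. These defaults are
# a reconstruction of common claims practice and are meant to be overridden
# by site-specific code lists.
comorbidities:
  renal_dysfunction: [N17, N18, N19]
  liver_dysfunction: [K70, K71, K72, K73, K74, K75, K76, K77]
  cardiac_dysfunction: [I20, I21, I22, I23, I24, I25, I30, I31, I32, I33, I34,
                        I35, I36, I37, I38, I39, I40, I41, I42, I43, I44, I45,
                        I46, I47, I48, I49, I50, I51, I52]
  pulmonary_dysfunction: [J40, J41, J42, J43, J44, J45, J46, J47, J96]
  vascular_disorder: [I10, I11, I12, I13, I14, I15, I70, I71, I72, I73, I74,
                      I75, I76, I77, I78, I79]
  back_pain: [M54]
  dementia: [F00, F01, F02, F03, G30]
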