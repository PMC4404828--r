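# Default functional-category map for the rank-based trend analysis.
# Each entry: parameter-table column name + whether the ranking direction is
# inverted (inv: low raw value -> high rank).
general_activity:
  - {parameter: TOTAL_ACT, inverse: false}
  - {parameter: FRQ_total_corr, inverse: false}
  - {parameter: DURFRQ_total_corr, inverse: true}
  - {parameter: FRQ_center, inverse: false}
  - {parameter: DIST_arena, inverse: false}
exploratory_activity:
  - {parameter: DUR_total_corr, inverse: true}
  - {parameter: DUR_center, inverse: true}
  - {parameter: DUR_hurdle, inverse: false}
  - {parameter: rearings, inverse: false}
  - {parameter: nose_pokes, inverse: false}
shelter_seeking:
  - {parameter: FRQ_dcr, inverse: false}
  - {parameter: DUR_dcr, inverse: false}
  - {parameter: DURFRQ_dcr, inverse: false}
risk_assessment:
  - {parameter: saps, inverse: false}
  - {parameter: DURFRQ_slope, inverse: false}
  - {parameter: DURFRQ_be, inverse: false}
risk_taking:
  - {parameter: FRQ_bridge, inverse: false}
  - {parameter: DUR_bridge, inverse: false}
  - {parameter: DURFRQ_bridge, inverse: false}
  - {parameter: FRQ_ctrci, inverse: false}
  - {parameter: DUR_ctrci, inverse: false}
  - {parameter: DURFRQ_ctrci, inverse: false}
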