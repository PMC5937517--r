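# Illustrative severity-grading configuration for common laboratory
# adverse events. The cut points below are SYNTHETIC example values in the
# shape of CTCAE v4.03 laboratory criteria; they are NOT the official
# CTCAE thresholds. Users grading real data must supply their own
# institution-approved table in this format.
#
# direction: below = lower values are more severe; above = higher.
# boundary_type:
#   absolute     - cut points in the test's native unit
#   ref_multiple - cut points as multiples of the reference limit
#                  (ref_low for "below" rules, ref_high for "above")
#   ref_offset   - cut points as offsets from the reference limit,
#                  applied in the severity direction
# boundaries: grade 1 first, up to grade 4; null = grade not defined.
rules:
  - ae_term: Anemia
    soc: Blood and lymphatic system disorders
    test_code: HGB          # g/dL
    direction: below
    boundary_type: absolute
    boundaries: [12.0, 10.0, 8.0, null]
  - ae_term: Neutrophil count decreased
    soc: Investigations
    test_code: "NEUT#"      # 10^9/L
    direction: below
    boundary_type: absolute
    boundaries: [1.8, 1.5, 1.0, 0.5]
  - ae_term: White blood cell decreased
    soc: Investigations
    test_code: WBC          # 10^9/L
    direction: below
    boundary_type: absolute
    boundaries: [3.8, 3.0, 2.0, 1.0]
  - ae_term: Platelet count decreased
    soc: Investigations
    test_code: PLT          # 10^9/L
    direction: below
    boundary_type: absolute
    boundaries: [125.0, 75.0, 50.0, 25.0]
  - ae_term: Alanine aminotransferase increased
    soc: Investigations
    test_code: ALT
    direction: above
    boundary_type: ref_multiple   # multiples of the upper reference limit
    boundaries: [1.0, 3.0, 5.0, 20.0]
  - ae_term: Aspartate aminotransferase increased
    soc: Investigations
    test_code: AST
    direction: above
    boundary_type: ref_multiple
    boundaries: [1.0, 3.0, 5.0, 20.0]
  - ae_term: Hyperglycemia
    soc: Metabolism and nutrition disorders
    test_code: GLU          # mmol/L
    direction: above
    boundary_type: absolute
    boundaries: [6.1, 8.9, 13.9, 27.8]
  - ae_term: Hypocalcemia
    soc: Metabolism and nutrition disorders
    test_code: CA           # mmol/L
    direction: below
    boundary_type: absolute
    boundaries: [2.0, 1.75, 1.5, 1.25]
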