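# WHO-UMC causality decision table. Facts:
#   temporal_plausibility: yes | no | unknown
#   alternative_causes:    excluded | present | unknown
#   dechallenge:           positive | negative | none
#   rechallenge:           positive | negative | none
#   data_sufficient:       true | false
# Rules are evaluated top to bottom; "any" matches every value. A positive
# rechallenge with data_sufficient = false is contradictory and rejected in
# code before the table is consulted.
rules:
  - when: {data_sufficient: "false"}
    category: unassessable_unclassifiable
  - when: {temporal_plausibility: "yes", alternative_causes: excluded,
           dechallenge: positive, rechallenge: positive}
    category: certain
  - when: {temporal_plausibility: "yes", alternative_causes: excluded,
           dechallenge: positive}
    category: probable
  - when: {temporal_plausibility: "no"}
    category: unlikely
  - when: {temporal_plausibility: unknown}
    category: conditional_unclassified
  - when: {temporal_plausibility: "yes"}
    category: possible
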