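# Adapted Global Trigger Tool catalog for adult ICU surveillance.
# 28 triggers: medication (21), care (3), laboratory test results (4).
# All numeric thresholds are strict (a value exactly at the threshold does
# not fire). Thresholds are in the analyte units of the labs table.
triggers:
  - trigger_id: ptt_gt_50
    label: "PTT > 50"
    module: MEDICATION
    rule_kind: LAB_THRESHOLD
    analyte: PTT_s
    direction: GT
    threshold: 50
  - trigger_id: inr_gt_3
    label: "INR > 3"
    module: MEDICATION
    rule_kind: LAB_THRESHOLD
    analyte: INR
    direction: GT
    threshold: 3
  - trigger_id: glucose_lt_50
    label: "Blood glucose <50 mg/dL"
    module: MEDICATION
    rule_kind: LAB_THRESHOLD
    analyte: GLUCOSE_mg_dL
    direction: LT
    threshold: 50
  - trigger_id: bun_cr_rise_2x
    label: "Rising BUN or Serum Cr 2x over Baseline"
    module: MEDICATION
    rule_kind: RELATIVE_CHANGE
    mode: RISE_FOLD
    magnitude: 2
    analytes: [BUN_mg_dL, CREATININE_mg_dL]
  - trigger_id: ondansetron
    label: "Ondansetron"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [ondansetron]
  - trigger_id: bromopride
    label: "Bromopride"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [bromopride]
  - trigger_id: metoclopramide
    label: "Metoclopramide"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [metoclopramide]
  - trigger_id: phytomenadione
    label: "Phytomenadione"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [phytomenadione]
  - trigger_id: flumazenil
    label: "Flumazenil"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [flumazenil]
  - trigger_id: naloxone
    label: "Naloxone"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [naloxone]
  - trigger_id: protamine
    label: "Protamine"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [protamine]
  - trigger_id: dexchlorpheniramine
    label: "Dexchlorpheniramine"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [dexchlorpheniramine]
  - trigger_id: hydroxyzine
    label: "Hydroxyzine"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [hydroxyzine]
  - trigger_id: diphenhydramine
    label: "Diphenhydramine"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [diphenhydramine]
  - trigger_id: loratadine
    label: "Loratadine"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [loratadine]
  - trigger_id: hydrocortisone
    label: "Hydrocortisone"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [hydrocortisone]
  - trigger_id: methylprednisolone
    label: "Methylprednisolone"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [methylprednisolone]
  - trigger_id: promethazine
    label: "Promethazine"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [promethazine]
  - trigger_id: prednisone
    label: "Prednisone"
    module: MEDICATION
    rule_kind: MED_ADMINISTERED
    drugs: [prednisone]
  - trigger_id: oversedation_hypotension
    label: "Over-Sedation/Hypotension (MAP <70)"
    module: MEDICATION
    rule_kind: VITAL_THRESHOLD
    analyte: MAP_mmHg
    direction: LT
    threshold: 70
  - trigger_id: abrupt_medication_stop
    label: "Abrupt medication stop"
    module: MEDICATION
    rule_kind: ABRUPT_STOP
  - trigger_id: hb_ht_drop_25pct
    label: "Decrease in Hb/Ht of 25% or Greater"
    module: CARE
    rule_kind: RELATIVE_CHANGE
    mode: DROP_PCT
    magnitude: 0.25
    analytes: [HEMOGLOBIN_g_dL, HEMATOCRIT_pct]
  - trigger_id: patient_fall
    label: "Patient fall"
    module: CARE
    rule_kind: NOTE_EVENT
    note_kind: PATIENT_FALL
  - trigger_id: skin_rash
    label: "Skin Rash"
    module: CARE
    rule_kind: NOTE_EVENT
    note_kind: SKIN_RASH
  - trigger_id: sodium_lt_135
    label: "Sodium <135 mEq/L"
    module: LAB
    rule_kind: LAB_THRESHOLD
    analyte: SODIUM_mEq_L
    direction: LT
    threshold: 135
  - trigger_id: potassium_lt_3_0
    label: "Potassium <3.0 mmol/L"
    module: LAB
    rule_kind: LAB_THRESHOLD
    analyte: POTASSIUM_mmol_L
    direction: LT
    threshold: 3.0
  - trigger_id: potassium_gt_5_5
    label: "Potassium >5.5 mmol/L"
    module: LAB
    rule_kind: LAB_THRESHOLD
    analyte: POTASSIUM_mmol_L
    direction: GT
    threshold: 5.5
  - trigger_id: platelets_lt_50000
    label: "Platelets <50,000"
    module: LAB
    rule_kind: LAB_THRESHOLD
    analyte: PLATELETS_per_uL
    direction: LT
    threshold: 50000
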