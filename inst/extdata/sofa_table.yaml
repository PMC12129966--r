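# SOFA cut-points (six organ systems, subscores 0-4).
# lower_worse: subscore = number of breaks the value is strictly below.
# higher_worse: subscore = number of breaks the value is at or above.
# The cardiovascular subscore uses MAP plus vasopressor support because
# agent doses are not part of the data model: no support and MAP >= 70 -> 0,
# MAP < 70 -> 1, dopamine -> 2, norepinephrine or epinephrine -> 3, two or
# more concurrent vasopressor agents -> 4.
respiratory:
  variable: PAO2_FIO2_ratio
  direction: lower_worse
  breaks: [400, 300, 200, 100]
coagulation:
  variable: PLATELETS_per_uL
  direction: lower_worse
  breaks: [150000, 100000, 50000, 20000]
hepatic:
  variable: BILIRUBIN_mg_dL
  direction: higher_worse
  breaks: [1.2, 2.0, 6.0, 12.0]
cardiovascular:
  variable: MAP_mmHg
  map_threshold: 70
  support_scores:
    dopamine: 2
    catecholamine: 3
    multiple: 4
  vasopressors: [dopamine, norepinephrine, epinephrine]
neurological:
  variable: GCS_points
  direction: lower_worse
  breaks: [15, 13, 10, 6]
renal:
  variable: CREATININE_mg_dL
  direction: higher_worse
  breaks: [1.2, 2.0, 3.5, 5.0]
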