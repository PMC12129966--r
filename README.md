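# icutrigger

Trigger-based active surveillance of adverse drug reactions (ADRs) in adult
intensive care units.

Spontaneous reporting — staff voluntarily filing ADR notifications — misses
most events, dramatically so in ICUs. Trigger tools are the standard active
alternative: the chart is screened for predefined *triggers* (an abnormal
laboratory value such as glucose < 50 mg/dL, an antidote administration, an
abrupt stop of a scheduled drug, a documented rash or fall), and each hit
prompts a focused review of whether an ADR occurred. `icutrigger` implements
an ICU-adapted Global Trigger Tool pipeline for a two-unit setting (a
general ICU and a COVID-19 ICU), end to end:

* **EHR data model** — one ICU stay per patient with time-stamped labs,
  medication courses/administrations and clinical note events; delimited
  CSV readers/writers with row-level validation and the eligibility screen
  (adults over 18 admitted for more than 24 h with at least one prescribed
  medication).
* **Trigger engine** — a 28-trigger catalog in three modules (medication 21,
  care 3, laboratory 4), with strict thresholds, one hit per trigger per
  calendar day, and episode semantics for relative-change rules.
* **SOFA scoring** — six organ subscores (0–4) and totals (0–24) on a fixed
  grid with last observation carried forward.
* **Adjudication** — Naranjo causality (packaged points table; doubtful /
  possible / probable / definite at breaks 0/1, 4/5, 8/9), WHO-UMC causality
  (packaged decision table), WHO three-level severity, Rawlins–Thompson
  Type A/B mechanism, ATC drug coding, and a dual-reviewer merge with
  third-review tiebreak.
* **Surveillance metrics** — per-trigger performance: triggers per 100
  records, ADRs per 100 records, and the positive predictive value
  `PPV = 100 × (ADRs identified by the trigger) / (times the trigger fired)`,
  plus prevalence, detection-source breakdown, temporal quartiles of onset,
  and the underreporting rate against the spontaneous-report log.
* **Risk factors** — chi-square / Fisher / Mann–Whitney group comparisons
  and forward stepwise logistic regression with Wald 95% CIs.
* **Synthetic cohort generator** — the hospital records behind the published
  calibration are not redistributable, so the package generates cohorts with
  their statistical structure (unit mix, demographics, SOFA trajectories,
  per-trigger background rates, and embedded ground-truth ADRs with
  signature events), making every stage testable.

## Worked example

One call runs the whole pipeline on a synthetic 135-patient cohort at the
default calibration (identical seed ⇒ identical outputs):

```r
library(icutrigger)
res <- run_pipeline(default_config(), seed = 2020)
print(res$report)
#> Trigger-tool surveillance report
#>   records screened: 135
#>   patients with >=1 ADR: 63 (46.7%)
#>   total ADRs: 89 (75.3% trigger-detected)
#>   trigger hits: 1092 (8.1 per record)
#>   ICU mortality: 65.9%
#>   underreporting rate: 100.0%
#>   top triggers by PPV:
#>     PTT > 50                                  1.5 /100  PPV 100.0%
#>     Skin Rash                                 0.7 /100  PPV 100.0%
#>     Abrupt medication stop                   34.1 /100  PPV  39.1%
#>     Blood glucose <50 mg/dL                  68.9 /100  PPV  28.0%
#>     INR > 3                                   3.7 /100  PPV  20.0%
print(res$model)
#> Stepwise logistic regression (entry/stay p = 0.05 / 0.05 ), n = 135
#>   selected: los_days, unit
#>   los_days     OR 1.084 (95% CI 1.029-1.141), p = 0.002489
#>   unitC19_ICU  OR 3.190 (95% CI 1.513-6.730), p = 0.002315
```

Reading the output: 46.7% of the simulated patients had at least one ADR
(the calibrated prevalence is 40.7%; at n = 135 a single draw scatters
around it), records carried 8.1 trigger hits on average, and none of the
ADRs had a matching spontaneous report (100% underreporting, the calibrated
default). The triggers with perfect PPV fired rarely — every hit marked a
real ADR — while high-volume triggers such as glucose < 50 mg/dL identify
more ADRs in absolute terms at a much lower PPV. The risk model recovers
longer stays and admission to the COVID unit as ADR risk factors; the unit
odds ratio is generated at 2.379, and single-cohort estimates scatter
around it.

Individual stages are ordinary functions over data frames:

```r
sim  <- generate_cohort(default_config(), seed = 2020)  # cohort + ground truth
hits <- scan_cohort(sim$cohort)                         # trigger hits
adrs <- adjudicate_cohort(sim$cohort, hits)             # adjudicated ADRs
surveillance_report(sim$cohort, hits, adrs)             # metrics
```

`run_pipeline(out_dir = ...)` writes every stage's checkpoint (cohort CSVs,
`hits.csv`, `adrs.csv`, `performance.csv`, `ground_truth.csv`,
`report.json`, `stats.json`, a run manifest), and each stage can be re-run
from the files alone.

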