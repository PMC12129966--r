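---
title: "Trigger-based ADR surveillance in the ICU: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger-based ADR surveillance in the ICU: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icutrigger)
```

## The surveillance problem

Spontaneous reporting — staff voluntarily notifying adverse drug reactions
(ADRs) — is known to miss the overwhelming majority of events, especially in
intensive care where workload is high. Trigger tools are the standard active
alternative: instead of waiting for reports, the chart is screened for
predefined *triggers* — clues such as a blood glucose below 50 mg/dL, an
antidote administration, or an abrupt stop of a scheduled drug — and every
hit prompts a focused review of whether an ADR occurred. A trigger hit is a
*screening signal*, not a diagnosis; the fraction of hits that turn out to
be real ADRs is the trigger's positive predictive value (PPV).

`icutrigger` implements this workflow end to end for a two-unit adult ICU
setting (a general unit, G-ICU, and a COVID-19 unit, C19-ICU): a structured
EHR data model, a 28-trigger catalog adapted from the Global Trigger Tool,
adjudication of candidate ADRs (causality, severity, mechanism, ATC
coding), surveillance metrics, and an inferential layer for ADR risk
factors. Because the hospital records the calibration derives from are not
redistributable, the package ships a synthetic cohort generator that
reproduces their statistical structure, with embedded ground-truth ADRs, so
the full pipeline is testable.

## The trigger catalog

The catalog (`default_catalog()`) contains 28 triggers in three modules:
21 medication triggers (PTT > 50 s, INR > 3, glucose < 50 mg/dL, BUN or
creatinine rising 2x over the admission baseline, thirteen rescue /
antidote / hypersensitivity-management drug administrations, over-sedation
or hypotension with MAP < 70 mmHg, abrupt medication stop), 3 care triggers
(haemoglobin/haematocrit drop of 25% or more, patient fall, skin rash) and
4 laboratory triggers (Na < 135 mEq/L, K < 3.0 mmol/L, K > 5.5 mmol/L,
platelets < 50,000/uL). The PTT and INR thresholds are the ICU-adapted
values (50 s and 3), not the original GTT ones (100 s and 6); a site can
restore those by editing the YAML catalog asset.

Numerical conventions, fixed once and used everywhere:

* **Strict thresholds.** "Greater than 50 s" and "less than 50 mg/dL" are
  read literally: a value exactly at the threshold does not fire.
* **One hit per trigger per calendar day** (daily deduplication). Published
  trigger rates exceed 100 per 100 records, so multiple hits per record are
  expected, but counting every MAP measurement during continuous monitoring
  would be meaningless; day-level granularity matches chart-review
  practice. Note-event triggers (fall, rash) are exempt — each documented
  event is a distinct hit.
* **Episode semantics for relative changes.** The Hb/Ht drop rule compares
  each value against the running maximum of prior values and fires once per
  excursion episode, resetting only when the series recovers past the
  threshold — a three-day bleed is one hit, not three. The 2x-rise rule
  uses the admission (first) value as baseline.
* **Abrupt stop, operationalised narrowly.** A hit requires a *scheduled*
  course, a recorded intended end time, a stop before that intended end and
  more than 24 h before discharge (so stops explained by discharge or death
  are censored), and no administration of the same drug in the following
  24 h. Courses without intended-end metadata never fire. The source
  methodology does not give an operational definition; this is the
  narrowest auditable one.
* **MAP < 70 fires on its own.** Whether a sedative or opioid was running
  is recorded in the hit's evidence but is not a firing condition, matching
  the trigger's published labelling "(MAP < 70)".

## SOFA scoring

Organ failure is summarised with SOFA: six organ systems scored 0–4 from
PaO2/FiO2, platelets, bilirubin, MAP, Glasgow Coma Scale and creatinine,
total 0–24. The standard published cut-points are packaged as an editable
YAML asset. Scores are computed on a fixed grid from admission (default
every 24 h; the source charts documented scores at least every 48 h) with
last observation carried forward per variable, and 0 before a variable's
first observation (logged). Because the data model carries no vasopressor
doses, the cardiovascular subscore uses a dose-free surrogate: MAP >= 70
with no support scores 0, MAP < 70 scores 1, dopamine 2, norepinephrine or
epinephrine 3, and two or more concurrent agents 4. This is a documented
simplification of the dose-banded original.

## Adjudication

Candidate ADRs are characterised on four axes:

* **Naranjo causality**: the 10-question probability scale, scored from a
  packaged points table (so the weights are auditable and editable);
  categories doubtful (<= 0), possible (1–4), probable (5–8), definite
  (>= 9).
* **WHO-UMC causality**: a packaged first-match decision table over five
  structured facts (temporal plausibility, alternative causes,
  dechallenge, rechallenge, data sufficiency) mapping to the six WHO-UMC
  categories; adding supporting evidence never weakens the category, and a
  positive rechallenge with insufficient data is rejected as
  contradictory.
* **WHO severity**: three boolean facts operationalise the three-level
  wording — severe if life-threatening or causing/prolonging
  hospitalisation, moderate if an intervention or therapy change was
  needed, else mild.
* **Rawlins–Thompson mechanism**: Type A iff dose-dependent *and*
  pharmacologically predictable, else Type B.

Suspected drugs are coded with a packaged ATC mini-dictionary (the
calibration study's suspect drugs plus all trigger-list drugs), through a
synonym table, case-insensitively.

The human path is dual review: two independent `merge_reviews()` inputs,
field-wise agreement, divergence settled by a third review, divergence
without one an error naming the fields. The automated path consumes
*structured ADR assessment notes* — note events whose text is a
machine-parseable key=value record of the assessment facts. In the
synthetic cohorts these notes stand in for the study's human chart review;
`adjudicate_cohort()` re-derives every classification from the recorded
facts through the same classification functions, so on synthetic data the
adjudicated labels must equal the embedded ground truth exactly, and the
tests assert that they do.

**Detection linkage.** An adjudicated ADR is attributed to a trigger when a
clinically relevant trigger fired on the onset day (preferred) or within
one day: reaction-specific analyte triggers first (hypoglycaemia to
glucose < 50, hyperkalaemia to K > 5.5, bleeding to
protamine/phytomenadione/INR/PTT/platelets/Hb-drop in that specificity
order, ...), then an abrupt stop of the suspected drug; otherwise the ADR
counts as found by non-trigger review. Antiemetic administration triggers
are deliberately excluded from the relevance map: their background rates
are high enough that nausea/vomiting ADRs would frequently be
mis-attributed to coincidental antiemetic doses.

## Surveillance metrics

All table outputs are computed from integer counts and only rounded (half
away from zero) to one decimal for display: triggers per 100 records
(100 x hits / records), ADRs per 100 records (100 x trigger-identified
ADRs / records) and PPV = 100 x ADR count / hit count, which equals the
ratio of the *unrounded* rates — computing it from the rounded printed
rates would compound rounding error. PPV of a never-firing trigger is
defined as 0. Prevalence counts patients with at least one ADR, not ADRs.
The temporal position of an onset within a stay is
`ceiling(4 * onset_day / los_days)` clamped to 1..4. The underreporting
rate is the share of ADRs with no spontaneous report matching on patient
and synonym-normalised drug.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are the published
calibration and are not tuning knobs:

* 135 patients, 76/135 in the G-ICU; per-unit age 60.5 +/- 15.6 vs
  62.3 +/- 14.5 years (normal, truncated to 19–100, rounded); length of
  stay 12.2 +/- 10.9 vs 13.8 +/- 11.0 days (log-normal matched to
  mean/SD — stay distributions are right-skewed with SD close to the
  mean — truncated above 1 day); male fraction 39/76 vs 35/59; ICU
  mortality 94/135.
* ADR carriage via a logistic model with the published odds structure
  (OR 2.379 for the COVID unit, 1.039 per year, 1.100 per day of stay); the
  intercept is calibrated on the drawn covariates so the expected
  prevalence equals 55/135. Affected patients carry a truncated-geometric
  number of ADRs with mean 85/55 (only the totals are published; the
  geometric is a stated assumption). Onset days follow Beta(2, 2) over the
  stay fraction, concentrating onsets in the middle quartiles of the stay.
* Templates: the published drug–reaction pairs with their counts as
  sampling weights, each with a clinically coherent signature trigger
  (21/85 have none and are detectable only by note review) and embedded
  classification facts matching the published severity (12/48/25),
  mechanism (82 A / 3 B), Naranjo (55/29/1) and WHO-UMC (53/30/1/1)
  margins.
* Background ("noise") trigger events at the published per-trigger rate
  minus its ADR-linked share, Poisson per record, placed on distinct days.
* SOFA trajectories: an admission total drawn from N(8.0, 4.6), an
  outcome-dependent drift (+0.25/day for deaths, -0.35/day for survivors)
  plus a small random walk, allocated across organs by per-patient
  propensities and inverted through the cut-point table into daily
  laboratory values. These constants were set once so that the cohort mean
  of per-patient mean totals reproduces the published 8.4.

Timing conventions make the pieces compose cleanly: routine daily labs sit
exactly on the SOFA grid (admission instant + 24 h steps); abnormal
excursions sit between grid points (+10 h, recovering +16 h) so they fire
triggers without distorting the SOFA trajectory; and all of an embedded
ADR's signature events share the assessment note's +12 h offset so they
fall on the same calendar hospital day as the recorded onset.

`expected_performance()` returns the per-trigger hit rates, ADR-linked
rates and PPVs *implied by a configuration* (background + template mix).
Realised rates run very slightly below these expectations because two
same-day events deduplicate to one hit and very short stays truncate the
Poisson counts; recovery tests therefore allow 3 SE plus a 2-percentage-
point allowance fixed a priori for these approximations.

What the generator does **not** emulate: real physiology (values are drawn
uniformly within score bands), drug–drug interactions, inter-variable
correlation beyond the SOFA trajectory, COVID-19 disease dynamics, or
free-text notes. Passing recovery tests therefore show that the *pipeline*
is correct and well calibrated, not that it would achieve the same PPVs on
real charts.

## Inferential layer

Unit and ADR/no-ADR comparisons use the chi-square test for categorical
variables, switching to Fisher's exact test when any expected cell count
is below 5, and the two-sided Mann–Whitney U test for quantitative ones
(exact for group sizes up to 20 without ties, normal approximation with
tie and continuity correction otherwise). Risk factors are selected by
forward stepwise logistic regression with entry/stay thresholds of
0.05/0.05 (the source states only "stepwise selection" at the 5% level;
direction and thresholds are this package's documented choice, and both
are arguments). Entry uses the likelihood-ratio test; a backward check
removes variables whose Wald p rises above the stay threshold, and a
variable removed this way is not re-entered, which guarantees termination.
Odds ratios are reported with Wald 95% confidence intervals. Perfect
collinearity and complete separation are detected and rejected with
diagnostics rather than reported as estimates.

The published Tables' exact p-values and confidence intervals are *not*
reproducible — they require the original patient-level data — so the tests
check parameter recovery instead: on synthetic cohorts the unit effect is
generated at OR 2.379 and the mean estimate over replicates must fall in
[2.0, 2.9], with 95% CI coverage between 90% and 99%.

## Degenerate inputs and edge policies

* A 25-hour stay is eligible ("more than 24 h") and reports as 2 whole
  days: whole-day summaries use the ceiling of fractional days.
* Ineligible records are excluded with a logged reason, never an error;
  malformed rows are collected as violations with file line numbers.
* An empty cohort produces headers-only files and an empty report with a
  warning; zero ADRs make the underreporting rate undefined (`NA`).
* Administrations that match no course window, lab values outside
  physiological bounds (negative counts, GCS outside 3–15, MAP >= 300) and
  malformed ATC codes are violations.
* Stays are generated wholly inside the study year; how stays spanning the
  study boundary were handled in the source is unstated, and the generator
  avoids the case.

## Problem sizes used by the tests

The packaged checks run the default 135-patient calibration for
cohort-level statistics, 1,200–2,000 patients for signature-recovery and
PPV-recovery checks, 5,000 patients for demographic calibration recovery,
and 50–200 replicates for risk-model recovery and CI coverage. These sizes
were chosen to make 3-SE bands decisively tighter than the effects being
checked while keeping the whole suite runnable on a laptop in a few
minutes.
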