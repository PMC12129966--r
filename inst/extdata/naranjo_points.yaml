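# Naranjo ADR probability scale: per-question points for yes / no / unknown.
questions:
  - id: 1
    text: "Are there previous conclusive reports on this reaction?"
    "yes": 1
    "no": 0
    unknown: 0
  - id: 2
    text: "Did the adverse event appear after the suspected drug was administered?"
    "yes": 2
    "no": -1
    unknown: 0
  - id: 3
    text: "Did the adverse reaction improve when the drug was discontinued or a specific antagonist was administered?"
    "yes": 1
    "no": 0
    unknown: 0
  - id: 4
    text: "Did the adverse reaction reappear when the drug was readministered?"
    "yes": 2
    "no": -1
    unknown: 0
  - id: 5
    text: "Are there alternative causes that could on their own have caused the reaction?"
    "yes": -1
    "no": 2
    unknown: 0
  - id: 6
    text: "Did the reaction reappear when a placebo was given?"
    "yes": -1
    "no": 1
    unknown: 0
  - id: 7
    text: "Was the drug detected in the blood in concentrations known to be toxic?"
    "yes": 1
    "no": 0
    unknown: 0
  - id: 8
    text: "Was the reaction more severe when the dose was increased, or less severe when the dose was decreased?"
    "yes": 1
    "no": 0
    unknown: 0
  - id: 9
    text: "Did the patient have a similar reaction to the same or similar drugs in any previous exposure?"
    "yes": 1
    "no": 0
    unknown: 0
  - id: 10
    text: "Was the adverse event confirmed by any objective evidence?"
    "yes": 1
    "no": 0
    unknown: 0
categories:
  definite: 9     # score >= 9
  probable: 5     # 5..8
  possible: 1     # 1..4
  doubtful: 0     # <= 0
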