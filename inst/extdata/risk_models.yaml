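# Environmental risk-factor odds-ratio models (13 factors).
# SYNTHETIC configuration of realistic magnitude: the curve shapes and
# values are package-chosen defaults, not transcriptions of any published
# per-factor table. Continuous bins are half-open [low, high); keys are
# lower bounds, the last bin is open above. The age curve uses a
# reference age of 20 and dominates the aggregate OR in a late
# middle-aged cohort.
factors:
  - factor_id: age
    kind: continuous
    age_dependent: true
    ors: {"20": 1.0, "25": 1.3, "30": 1.7, "35": 2.4, "40": 4.0,
          "45": 7.0, "50": 11.5, "55": 18.5, "60": 27.0, "65": 36.0,
          "70": 43.0}
  - factor_id: bmi
    kind: continuous
    ors: {"0": 1.0, "25": 1.4, "30": 2.3, "35": 3.5}
  - factor_id: waist
    kind: continuous
    ors: {"0": 1.0, "94": 1.3, "102": 1.7}
  - factor_id: gender
    kind: categorical
    ors: {female: 1.0, male: 1.3}
  - factor_id: ethnicity
    kind: categorical
    ors: {european: 1.0, south_asian: 1.9, east_asian: 1.3,
          african: 1.5, other: 1.2}
  - factor_id: smoking
    kind: categorical
    ors: {never: 1.0, past: 1.15, current_sometimes: 1.3,
          current_regularly: 1.6}
    source_measure: RR
    p0: 0.08
  - factor_id: past_smoking
    kind: categorical
    ors: {"no": 1.0, "yes": 1.05}
  - factor_id: alcohol
    kind: continuous
    # drinks/week; moderate intake protective relative to abstention
    ors: {"0": 1.0, "0.5": 0.85, "14": 1.0, "21": 1.25}
  - factor_id: hypertension
    kind: categorical
    ors: {normal: 1.0, high_normal: 1.15, stage1: 1.4, stage2: 1.9}
    medication_overrides: [on_antihypertensive]
    source_measure: HR
    p0: 0.07
  - factor_id: triglycerides
    kind: continuous
    ors: {"0": 1.0, "1.7": 1.5, "2.3": 2.0}
    medication_overrides: [on_lipid_lowering]
  - factor_id: hdl
    kind: continuous
    ors: {"0": 1.8, "1.03": 1.15, "1.55": 1.0}
    medication_overrides: [on_lipid_lowering]
  - factor_id: physical_activity
    kind: categorical
    ors: {very_low: 1.2, low: 1.05, moderate: 1.0}
    source_measure: RR
    p0: 0.09
  - factor_id: family_history
    kind: categorical
    role: family_history
    ors: {none: 1.0, one: 1.8, two: 3.2}
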