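# SYNTHETIC PLACEHOLDER point table in the style of the Finnish
# (FINDRISC-type) diabetes risk score. The bin layout follows the
# published score's variables; the point values here are placeholders to
# exercise the machinery — transcribe the published coefficients before
# any substantive use.
name: finnish_findrisc_synthetic
variables:
  - factor: age
    kind: continuous
    points: {"0": 0, "45": 2, "55": 3, "65": 4}
  - factor: bmi
    kind: continuous
    points: {"0": 0, "25": 1, "30": 3}
  - factor: waist
    kind: continuous
    points: {"0": 0, "94": 3, "102": 4}
  - factor: physical_activity
    kind: categorical
    points: {very_low: 2, low: 1, moderate: 0}
  - factor: hypertension
    kind: categorical
    points: {normal: 0, high_normal: 0, stage1: 2, stage2: 2}
  - factor: family_history
    kind: categorical
    points: {none: 0, one: 5, two: 5}
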