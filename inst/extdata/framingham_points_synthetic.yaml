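# SYNTHETIC PLACEHOLDER point table in the style of the Framingham
# Offspring diabetes risk score. Bin layout mirrors the published
# score's variables; point values are placeholders to exercise the
# machinery — transcribe the published coefficients before any
# substantive use.
name: framingham_offspring_synthetic
variables:
  - factor: age
    kind: continuous
    points: {"0": 0, "50": 1, "60": 2}
  - factor: gender
    kind: categorical
    points: {female: 0, male: 1}
  - factor: bmi
    kind: continuous
    points: {"0": 0, "25": 1, "30": 2}
  - factor: hdl
    kind: continuous
    # low HDL scores points
    points: {"0": 2, "1.0": 1, "1.3": 0}
  - factor: triglycerides
    kind: continuous
    points: {"0": 0, "1.7": 1, "2.3": 2}
  - factor: hypertension
    kind: categorical
    points: {normal: 0, high_normal: 1, stage1: 2, stage2: 3}
  - factor: family_history
    kind: categorical
    points: {none: 0, one: 2, two: 3}
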