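level_scores:
  not_met: 0.0
  partially_met: 1.0
  met_minimum: 2.0
  met_preferred: 3.0
  unknown: 0.0
weights:
  setting: 1.0
  efficacy: 2.0
  companion_diagnostic: 1.0
  clinical_monitoring: 1.0
  safety: 2.0
  mode_of_administration: 1.0
  treatment_adherence: 1.0
  stability: 1.0
  who_eml: 1.0
thresholds:
  I:
    high: 0.6
    medium: 0.4
  II:
    high: 0.6
    medium: 0.4
  III:
    high: 0.6
    medium: 0.4
  IV:
    high: 0.6
    medium: 0.4
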