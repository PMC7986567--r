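# step + ramp impact beginning January 2014 (h = 0, r = 0 for both)
interventions:
  - {shape: step, onset: 2014-01, label: step}
  - {shape: ramp, onset: 2014-01, label: ramp}
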