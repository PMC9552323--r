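alpha_beta: 1.93
v_ref: 1.0
categories:
- name: GS6
  d50: 48.0
  gamma50: 2.5
- name: GS7
  d50: 60.0
  gamma50: 2.5
- name: GS8
  d50: 70.0
  gamma50: 2.5
- name: GS9
  d50: 80.0
  gamma50: 2.5
adc_mapping:
  cutpoints:
  - 900.0
  - 750.0
  - 600.0
  width: 80.0
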