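population:
  size: 100000
  background_risk: 0.125
platform:
  sens_indel: 0.8
  sens_snv: 0.97
  sens_cnv: 0.0
  spec_indel: 1.0
  spec_snv: 1.0
  spec_cnv: 1.0
genes:
- name: BRCA1
  prevalence: 0.0012
  coverage: 0.9941
  spectrum:
    indel: 0.54
    snv: 0.36
    cnv: 0.1
  penetrance:
    central: 0.59
    low: 0.57
    high: 0.71
- name: BRCA2
  prevalence: 0.002
  coverage: 0.9997
  spectrum:
    indel: 0.69
    snv: 0.21
    cnv: 0.1
  penetrance:
    central: 0.51
    low: 0.45
    high: 0.875
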