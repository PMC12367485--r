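yeast_powder:
  unit: g/L
  role: medium_component
  levels:
  - 7.0
  - 10.0
  - 13.0
  - 16.0
  - 19.0
ammonium_sulfate:
  unit: g/L
  role: medium_component
  levels:
  - 1.0
  - 1.5
  - 2.0
  - 2.5
  - 3.0
glutamic_acid:
  unit: g/L
  role: medium_component
  levels:
  - 0.5
  - 1.0
  - 1.5
  - 2.0
  - 2.5
tyrosine:
  unit: g/L
  role: medium_component
  levels:
  - 0.5
  - 1.0
  - 1.5
  - 2.0
  - 2.5
calcium_chloride:
  unit: g/L
  role: medium_component
  levels:
  - 0.2
  - 0.3
  - 0.4
  - 0.5
  - 0.6
temperature:
  unit: degC
  role: process_parameter
  levels:
  - 26.0
  - 27.0
  - 28.0
  - 29.0
inoculum:
  unit: '%'
  role: process_parameter
  levels:
  - 0.1
  - 0.3
  - 0.5
  - 0.7
  - 0.9
pH:
  unit: ''
  role: process_parameter
  levels:
  - 6.1
  - 6.3
  - 6.5
  - 6.7
  - 6.9
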