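yeast_powder:
  unit: g/L
  role: medium_component
  levels:
  - 5.0
  - 7.0
  - 9.0
ammonium_sulfate:
  unit: g/L
  role: medium_component
  levels:
  - 0.5
  - 1.0
glutamic_acid:
  unit: g/L
  role: medium_component
  levels:
  - 0.5
  - 1.0
tyrosine:
  unit: g/L
  role: medium_component
  levels:
  - 2.0
  - 2.5
  - 3.0
temperature:
  unit: degC
  role: process_parameter
  levels:
  - 28.0
  - 29.0
  - 30.0
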