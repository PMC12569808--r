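# Box-Behnken factors for wet granulation, natural units:
# diluent in parts per 10 g extract, ethanol volume fraction and binder
# amount in percent.
factors:
  - {name: diluent, low: 6, center: 10, high: 14, units: parts}
  - {name: ethanol, low: 80, center: 85, high: 90, units: "%"}
  - {name: binder, low: 10, center: 12, high: 14, units: "%"}
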