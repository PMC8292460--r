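{
  "area_um2": {"min": 21000, "max": 29000},
  "circularity": {"min": 0.815},
  "preferred": {"feature": "area_um2", "value": 25000}
}
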