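{
  "A_c_km2": 4810,
  "A_f_km2": 4529,
  "A_fc_km2": 3823
}
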