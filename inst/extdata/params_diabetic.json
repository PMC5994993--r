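{
  "R0": 2.5,
  "EG0": 0.0025,
  "SI": 0.00114,
  "alpha": 10000,
  "Imax": 0.93,
  "ksto": 0.026,
  "kgut_liquid": 0.026,
  "Gss": 195,
  "Iss": 12.5
}
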