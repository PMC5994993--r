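{
  "R0": 2.1,
  "EG0": 0.001,
  "SI": 0.00306,
  "alpha": 10000,
  "Imax": 0.28,
  "ksto": 0.036,
  "kgut_liquid": 0.098,
  "kgut_mixed": 0.011,
  "Gss": 90,
  "Iss": 12.4
}
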