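{
  "name": "baseline_c2",
  "params": {
    "rho": 0.9,
    "delta": 0.1,
    "l": 1,
    "b1": 1,
    "b2": 1,
    "c1": 2,
    "c2": 2,
    "CO": 10,
    "a1": 2,
    "a2": 2,
    "cS": 3,
    "betaS": 1.5,
    "aS": 1.2,
    "bI": 2.5,
    "CI": 3,
    "x0_gov": 1,
    "x0_ent": 1
  },
  "sweep": {
    "c_unit": [2, 4]
  }
}
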