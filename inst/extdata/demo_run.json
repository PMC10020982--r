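{
  "K": 100,
  "clones": [
    {"b": 0.1, "u": 0.2, "r": 1.0, "d_A": 0.5, "d_I": 1.0, "label": "HSC"}
  ],
  "init": "equilibrium",
  "t_span": [0, 400],
  "events": [
    {"time": 1, "kind": "scale_param", "clone": 1, "target": "u", "magnitude": 2}
  ],
  "rtol": 1e-9,
  "atol": 1e-12
}
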