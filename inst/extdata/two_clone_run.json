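{
  "K": 100,
  "clones": [
    {"b": 0.1, "u": 0.2, "r": 1.0, "d_A": 0.5, "d_I": 1.0, "label": "healthy"},
    {"b": 0.1, "u": 0.2, "r": 1.2, "d_A": 0.5, "d_I": 1.0, "label": "mutated"}
  ],
  "t_span": [0, 3000]
}
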