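{
  "params": {
    "K": 100,
    "clones": [
      {"b": 0.1, "u": 0.2, "r": 1.0, "d_A": 0.5, "d_I": 1.0, "label": "HSC"}
    ]
  },
  "free": ["b", "u"],
  "init": {"kill_fraction": 0.5},
  "start": {"b": 0.15, "u": 0.3},
  "max_iter": 400,
  "seed": 11
}
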