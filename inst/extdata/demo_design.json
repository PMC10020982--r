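{
  "params": {
    "K": 100,
    "clones": [
      {"b": 0.1, "u": 0.2, "r": 1.0, "d_A": 0.5, "d_I": 1.0, "label": "HSC"}
    ]
  },
  "experiment": "recovery_after_depletion",
  "times": [1, 4, 7, 10, 13, 16, 19, 22, 25, 28, 31, 34, 37, 40],
  "sigma": 0,
  "kill_fraction": 0.5,
  "seed": 5
}
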