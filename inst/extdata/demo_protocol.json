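{
  "host": {
    "K": 100,
    "clones": [
      {"b": 0.1, "u": 0.2, "r": 1.0, "d_A": 0.5, "d_I": 1.0, "label": "host"}
    ]
  },
  "donor": {"b": 0.1, "u": 0.2, "r": 1.0, "d_A": 0.5, "d_I": 1.0, "label": "donor"},
  "total_dose": 20,
  "n_doses": 4,
  "dose_interval": 1,
  "preconditioning_fraction": 0,
  "endpoint": 365
}
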