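{
  "stages": ["synth", "pmf", "fep", "struct", "ephys"],
  "synth": {
    "n_steps_per_window": 20000
  },
  "pmf": {
    "z_min": -4,
    "z_max": 4,
    "spacing": 1,
    "k": 2.5
  },
  "fep": {
    "n": 5000
  },
  "struct": {
    "n_frames": 120
  }
}
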