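{
  "shell_volume": 23561.9449019234,
  "ar": 1.6,
  "cell_volume_fraction": 0.92,
  "F0": 0.45,
  "shell_gain": 0.8,
  "noise_variance": 0.027,
  "dt": 5,
  "alpha_default": 0.75,
  "alpha_pairs": {
    "EMS:P2": 0.9
  },
  "orientation_class": "T-div",
  "timing_mode": "asynchronous",
  "volume_mode": "asymmetric",
  "t_first": 300,
  "interval": 120,
  "settle": 600,
  "offset": 2,
  "ab_fraction": 0.6,
  "aba_fraction": 0.55,
  "ems_fraction": 0.6,
  "ar_min": 1,
  "ar_max": 4,
  "ar_step": 0.1,
  "n_reps": 30
}
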