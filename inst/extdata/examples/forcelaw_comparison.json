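{
  "curve": {"kind": "circle", "R": 1},
  "N": 8, "m": 2,
  "force_law": "inverse_density_sq", "k_star": 1, "eta_star": 1,
  "a_star": 0.7853981633974483, "offset_fraction": 0.5,
  "dt": 0.001, "t_end": 0.05, "save_times": [0.05], "J": 1000,
  "out": "forcelaw_pm.csv"
}
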