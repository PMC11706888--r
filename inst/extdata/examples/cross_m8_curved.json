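{
  "curve": {"kind": "polar_cross", "R0": 1},
  "model": "curved", "N": 8, "m": 8,
  "force_law": "hookean", "k_star": 1, "eta_star": 1,
  "a_star": "stress_free", "offset_fraction": 0.5,
  "dt": 0.001, "t_end": 12, "save_times": [0, 1, 4, 12],
  "out": "cross_m8_curved.csv"
}
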