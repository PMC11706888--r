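{
  "curve": {"kind": "polar_cross", "R0": 1},
  "model": "straight", "N": 8, "m": 1,
  "force_law": "hookean", "k_star": 1, "eta_star": 1,
  "a_star": "stress_free", "offset_fraction": 0.5,
  "dt": 0.001, "t_end": 100, "save_times": [0, 1, 10, 100],
  "out": "cross_m1_straight.csv"
}
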