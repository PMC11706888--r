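{
  "curve": {"kind": "circle", "R": 1},
  "model": "straight", "N": 4, "m": 1,
  "force_law": "hookean", "k_star": 1, "eta_star": 1,
  "a_star": "stress_free", "offset_fraction": 0.5,
  "dt": 0.001, "t_end": 10, "save_times": [0, 0.5, 2, 10],
  "out": "circle_straight.csv"
}
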