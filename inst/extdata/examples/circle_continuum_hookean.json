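{
  "curve": {"kind": "circle", "R": 1},
  "N": 8, "m": 4,
  "force_law": "hookean", "k_star": 1, "eta_star": 1,
  "a_star": 0.7853981633974483, "offset_fraction": 0.5,
  "t_end": 2, "save_times": [0.02, 0.2, 2], "J": 1000,
  "out": "circle_continuum_hookean.csv"
}
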