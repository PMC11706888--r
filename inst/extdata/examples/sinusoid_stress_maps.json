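{
  "curve": {"kind": "sinusoid", "R": 0.8},
  "model": "curved", "N": 4, "m": 4,
  "force_law": "hookean", "k_star": 1, "eta_star": 1,
  "a_star": 1.7979849847537634, "offset_fraction": 0.5,
  "dt": 0.001, "t_end": 4, "save_times": [0, 4],
  "out": "sinusoid_stress.csv"
}
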