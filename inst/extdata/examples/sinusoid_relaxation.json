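{
  "curve": {"kind": "sinusoid", "R": 0.8},
  "model": "curved", "N": 4, "m": 4,
  "force_law": "hookean", "k_star": 1, "eta_star": 1,
  "a_star": "stress_free", "offset_fraction": 0.5,
  "dt": 0.001, "t_end": 6.5, "save_times": [0, 0.5, 1.5, 4, 6.5],
  "out": "sinusoid_relaxation.csv"
}
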