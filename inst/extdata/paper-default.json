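{
  "cell": { "alpha": 0.65, "gNa_max": 2.4, "gs_max": 0.045,
            "k_K1_base": 0.5, "gNaC": 0.003, "ENa": 50 },
  "grid": { "nx": 120, "ny": 120, "nz": 1, "h": 0.1 },
  "sim": { "dt": 0.1, "duration": 3000, "sample_dt": 5 },
  "protocol": { "nx": 60, "ny": 80, "nz": 1, "h": 0.1,
                "D0": 0.0025, "Dmin": 0, "alpha_top": 0.6,
                "alpha_bottom": 0, "width": 2, "alpha_shift": 2,
                "u": -0.002, "nu": 0.25, "dt": 0.1 },
  "forces": { "spiral": { "alpha": 0.65, "D": 0.0025, "n": 120 } },
  "transition": { "alpha_list": [0.5, 0.6], "nu_bracket": [0.01, 0.5],
                  "D": 0.0025, "trials": 3 }
}
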