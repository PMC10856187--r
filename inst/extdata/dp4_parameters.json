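{
  "mPW1PW91/6-311+G(d,p)": {
    "provenance": "Package defaults. Scaled-branch Student-t statistics from Smith & Goodman, J. Am. Chem. Soc. 2010, 132, 12946 (13C sigma 2.306 ppm nu 11.38; 1H sigma 0.185 ppm nu 14.18; mu 0 by the scaled-error convention). Unscaled-branch spreads are package estimates for GIAO mPW1PW91 shielding errors; replace with the level-specific tables from the DP4+ supporting information (Grimblat, Zanardi & Sarotti, J. Org. Chem. 2015, 80, 12526) for publication-grade analyses.",
    "scaled": {
      "C": { "mu": 0.0, "sigma": 2.306, "nu": 11.38 },
      "H": { "mu": 0.0, "sigma": 0.185, "nu": 14.18 }
    },
    "unscaled": {
      "C_sp2": { "mu": 0.0, "sigma": 6.0, "nu": 6.0 },
      "C_sp3": { "mu": 0.0, "sigma": 6.0, "nu": 6.0 },
      "H": { "mu": 0.0, "sigma": 0.30, "nu": 8.0 }
    }
  }
}
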