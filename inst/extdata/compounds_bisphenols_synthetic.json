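{
  "_comment": [
    "Bisphenol parameter presets. Calibrated quantities (f_pc, phi,",
    "phi_chorion, sigma, Sat50) are the published maximum-posterior",
    "values. Tissue:water partition-coefficient PRIORS are a SYNTHETIC",
    "stand-in for the QSAR (VIVD) table, computed from a two-phase",
    "tissue-composition model P_i = f_water,i + f_lipid,i * Kow; the",
    "tissue water/lipid fractions below are literature-typical for the",
    "eleutheroembryo (lipid-rich yolk). phi/phi_chorion for BPAF/BPF/BPS",
    "are fixed to the BPA values (analog workflow). P_pw in 1/mm,",
    "F_polymer in uL/h/mm2; volatilization off for all bisphenols."
  ],
  "tissue_composition": {
    "yolk":     { "water": 0.45, "lipid": 0.300 },
    "liver":    { "water": 0.80, "lipid": 0.050 },
    "skeleton": { "water": 0.80, "lipid": 0.020 },
    "gut":      { "water": 0.80, "lipid": 0.030 },
    "eye":      { "water": 0.80, "lipid": 0.020 },
    "brain":    { "water": 0.80, "lipid": 0.060 },
    "heart":    { "water": 0.80, "lipid": 0.025 },
    "skin":     { "water": 0.80, "lipid": 0.030 },
    "muscle":   { "water": 0.80, "lipid": 0.015 },
    "other":    { "water": 0.80, "lipid": 0.020 }
  },
  "V_liver_cell": 1.5e-06,
  "compounds": {
    "BPA": {
      "MW": 228.29, "logKow": 3.32,
      "f_pc": 0.365, "phi": 8.00, "phi_chorion": 0.495, "sigma": 2.76,
      "Sat50_uM": null, "metabolism": "none",
      "F_polymer": 0.01, "P_pw": 0.5
    },
    "BPAF": {
      "MW": 336.23, "logKow": 4.47,
      "f_pc": 0.0164, "phi": 8.00, "phi_chorion": 0.495, "sigma": 1.07,
      "Sat50_uM": null, "metabolism": "none",
      "F_polymer": 0.01, "P_pw": 2.0
    },
    "BPF": {
      "MW": 200.23, "logKow": 2.91,
      "f_pc": 1.70, "phi": 8.00, "phi_chorion": 0.495, "sigma": 1.14,
      "Sat50_uM": 19.0, "metabolism": "none",
      "F_polymer": 0.01, "P_pw": 0.3
    },
    "BPS": {
      "MW": 250.27, "logKow": 1.65,
      "f_pc": 0.114, "phi": 8.00, "phi_chorion": 0.495, "sigma": 2.36,
      "Sat50_uM": null, "metabolism": "none",
      "F_polymer": 0.01, "P_pw": 0.05
    }
  }
}
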