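{
  "_comment": [
    "Default uniform prior bounds for the calibratable compound-specific",
    "parameters. The published prior table is supplementary-only; these",
    "bounds are package defaults chosen to bracket the reported",
    "posteriors by a wide margin. Sat50 in uM; K_met in uL/h per",
    "hepatocyte; sigma is a geometric SD (> 1)."
  ],
  "parameters": [
    { "parameter": "f_pc",        "lower": 0.01,  "upper": 10.0 },
    { "parameter": "phi",         "lower": 0.5,   "upper": 40.0 },
    { "parameter": "phi_chorion", "lower": 0.02,  "upper": 2.5 },
    { "parameter": "sigma",       "lower": 1.05,  "upper": 8.0 },
    { "parameter": "Sat50_uM",    "lower": 0.5,   "upper": 500.0 },
    { "parameter": "K_met",       "lower": 0.0,   "upper": 1.0e-3 }
  ]
}
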