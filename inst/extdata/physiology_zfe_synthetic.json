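{
  "_comment": [
    "SYNTHETIC reconstruction of the eleutheroembryo ontogeny parameter",
    "table (the published supplementary table is not redistributable).",
    "Values assembled from open zebrafish literature: embryo volume at",
    "120 hpf ~0.27 uL; yolk ~0.18 uL at fertilization, largely resorbed",
    "by 120 hpf; organogenesis onsets from staging series; organ volume",
    "fractions at 120 hpf encode final proportions via Kg_TR =",
    "ln(1 + fraction)/(120 - tau_TR); TA = 6930 K is the standard fish",
    "Arrhenius temperature. Growth-rate units 1/h, onsets hpf at 25 degC."
  ],
  "V_embryo_120": 0.27,
  "TA": 6930,
  "TR": 298.15,
  "t_fec": 0,
  "hatch_time": 48,
  "yolk": { "V0": 0.18, "k": 0.025 },
  "organs": [
    { "name": "liver",    "Kg_TR": 1.6919e-04, "tau_TR": 32 },
    { "name": "skeleton", "Kg_TR": 9.3442e-04, "tau_TR": 18 },
    { "name": "gut",      "Kg_TR": 4.3579e-04, "tau_TR": 30 },
    { "name": "eye",      "Kg_TR": 4.5176e-04, "tau_TR": 12 },
    { "name": "brain",    "Kg_TR": 6.1508e-04, "tau_TR": 10 },
    { "name": "heart",    "Kg_TR": 3.9920e-05, "tau_TR": 20 },
    { "name": "skin",     "Kg_TR": 1.0119e-03, "tau_TR": 8 },
    { "name": "muscle",   "Kg_TR": 3.3779e-03, "tau_TR": 10 },
    { "name": "other",    "Kg_TR": 1.2229e-03, "tau_TR": 5 }
  ]
}
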