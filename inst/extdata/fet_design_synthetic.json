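{
  "_comment": [
    "SYNTHETIC reconstruction of the fish-embryo-toxicity (FET, TG 236)",
    "style simulation design: one embryo per 24-well-plate well, 2 mL of",
    "medium renewed daily, 26 degC. Well geometry gives the polymer-water",
    "and air-water exchange surfaces. Replace this file if the original",
    "supplementary simulation constants become available."
  ],
  "V_water": 2000,
  "V_air": 2000,
  "S_pw": 450,
  "S_aw": 190,
  "n_embryos": 1,
  "temperature": 26,
  "renewal_every": 24,
  "duration": 144
}
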