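{
  "zmax_cm": 500,
  "density": 1,
  "histories": 200,
  "electrons": false,
  "threshold_eV": 1000,
  "type": "range",
  "energy_MeV": 30,
  "material": "water",
  "seed": 1
}
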