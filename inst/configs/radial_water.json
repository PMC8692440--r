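{
  "thickness_nm": 100,
  "density": 1,
  "histories": 100,
  "frac_cut": 0.001,
  "electrons": true,
  "type": "radial",
  "energy_MeV": 1,
  "material": "water",
  "seed": 1
}
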