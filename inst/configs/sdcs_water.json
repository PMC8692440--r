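{
  "thickness_nm": 10,
  "density": 9.97153709837895,
  "histories": 10000,
  "electrons": false,
  "type": "sdcs",
  "energy_MeV": 1,
  "material": "water",
  "seed": 1
}
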