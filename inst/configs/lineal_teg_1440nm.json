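{
  "R_nm": 1440,
  "nlat": 179,
  "angle_max_deg": 30,
  "density": 1,
  "histories": 200,
  "frac_cut": 0.005,
  "electrons": true,
  "ymax": 10,
  "type": "lineal",
  "energy_MeV": 30,
  "material": "teg",
  "seed": 1
}
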