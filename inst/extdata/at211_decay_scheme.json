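{
  "nuclide": "At-211",
  "half_life_h": 7.21,
  "branches": {
    "prob": [0.418, 0.582],
    "energy_MeV": [5.87, 7.45]
  },
  "photon_abundance_77_93keV": 0.43
}
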