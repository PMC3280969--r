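{
  "description": "Triple-layered rotavirus-like particle equilibrium model, stoichiometric scenario",
  "temperature_K": 298.15,
  "layers": [
    {
      "name": "vp2",
      "protein_mass_kDa": 102.7,
      "dg_kcal": -4.08,
      "s2": 3,
      "z": 2,
      "docked": false,
      "conc0_M": 1.2
    },
    {
      "name": "vp6",
      "protein_mass_kDa": 44.9,
      "dg_kcal": -4.08,
      "s2": 13,
      "z": 3,
      "docked": true,
      "conc0_M": 7.8
    },
    {
      "name": "vp7",
      "protein_mass_kDa": 37.2,
      "dg_kcal": -4.08,
      "s2": 13,
      "z": 3,
      "docked": true,
      "conc0_M": 7.8
    }
  ]
}
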