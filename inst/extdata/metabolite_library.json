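{
  "format": "lfnmr-metabolite-library-v1",
  "comment": "Spin-system parameters (chemical shifts in ppm, scalar couplings in Hz) for aqueous metabolite standards near neutral pH. Values follow GISSMO-optimized spin-system matrices cross-checked against HMDB reference shifts; third-decimal ppm agreement with any particular library version is not guaranteed. Multiplicity replicates a spin into magnetically equivalent copies (intra-group couplings set to zero; they do not affect the spectrum). Citrate is modelled as two independent geminal AB pairs (4 protons); TSP as a 9-proton singlet at 0.00 ppm.",
  "species": [
    {
      "name": "glucose_alpha",
      "source_id": "GISSMO bmse000015 / HMDB0000122 (alpha-D-glucopyranose)",
      "population": 0.36,
      "spins": [
        {"label": "H1", "shift_ppm": 5.216},
        {"label": "H2", "shift_ppm": 3.519},
        {"label": "H3", "shift_ppm": 3.698},
        {"label": "H4", "shift_ppm": 3.399},
        {"label": "H5", "shift_ppm": 3.822},
        {"label": "H6a", "shift_ppm": 3.826},
        {"label": "H6b", "shift_ppm": 3.749}
      ],
      "couplings": [
        [0.0, 3.8, 0.0, 0.0, 0.0, 0.0, 0.0],
        [3.8, 0.0, 9.8, 0.0, 0.0, 0.0, 0.0],
        [0.0, 9.8, 0.0, 9.2, 0.0, 0.0, 0.0],
        [0.0, 0.0, 9.2, 0.0, 10.0, 0.0, 0.0],
        [0.0, 0.0, 0.0, 10.0, 0.0, 2.3, 5.5],
        [0.0, 0.0, 0.0, 0.0, 2.3, 0.0, -12.3],
        [0.0, 0.0, 0.0, 0.0, 5.5, -12.3, 0.0]
      ]
    },
    {
      "name": "glucose_beta",
      "source_id": "GISSMO bmse000015 / HMDB0000122 (beta-D-glucopyranose)",
      "population": 0.64,
      "spins": [
        {"label": "H1", "shift_ppm": 4.634},
        {"label": "H2", "shift_ppm": 3.237},
        {"label": "H3", "shift_ppm": 3.473},
        {"label": "H4", "shift_ppm": 3.387},
        {"label": "H5", "shift_ppm": 3.450},
        {"label": "H6a", "shift_ppm": 3.882},
        {"label": "H6b", "shift_ppm": 3.707}
      ],
      "couplings": [
        [0.0, 7.9, 0.0, 0.0, 0.0, 0.0, 0.0],
        [7.9, 0.0, 9.3, 0.0, 0.0, 0.0, 0.0],
        [0.0, 9.3, 0.0, 9.2, 0.0, 0.0, 0.0],
        [0.0, 0.0, 9.2, 0.0, 9.8, 0.0, 0.0],
        [0.0, 0.0, 0.0, 9.8, 0.0, 2.2, 5.9],
        [0.0, 0.0, 0.0, 0.0, 2.2, 0.0, -12.3],
        [0.0, 0.0, 0.0, 0.0, 5.9, -12.3, 0.0]
      ]
    },
    {
      "name": "lactate",
      "source_id": "GISSMO bmse000208 / HMDB0000190 (L-lactate)",
      "population": 1.0,
      "spins": [
        {"label": "H2", "shift_ppm": 4.11},
        {"label": "CH3", "shift_ppm": 1.33, "multiplicity": 3}
      ],
      "couplings": [
        [0.0, 6.95],
        [6.95, 0.0]
      ]
    },
    {
      "name": "citrate",
      "source_id": "GISSMO bmse000458 / HMDB0000094 (citrate, two geminal CH2 AB pairs)",
      "population": 1.0,
      "spins": [
        {"label": "H2a", "shift_ppm": 2.67},
        {"label": "H2b", "shift_ppm": 2.53},
        {"label": "H4a", "shift_ppm": 2.67},
        {"label": "H4b", "shift_ppm": 2.53}
      ],
      "couplings": [
        [0.0, -15.1, 0.0, 0.0],
        [-15.1, 0.0, 0.0, 0.0],
        [0.0, 0.0, 0.0, -15.1],
        [0.0, 0.0, -15.1, 0.0]
      ]
    },
    {
      "name": "tsp",
      "source_id": "HMDB0062181 (trimethylsilylpropanoate-d4, 9-proton reference singlet)",
      "population": 1.0,
      "spins": [
        {"label": "Si(CH3)3", "shift_ppm": 0.0, "multiplicity": 9}
      ],
      "couplings": [[0.0]]
    }
  ]
}
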