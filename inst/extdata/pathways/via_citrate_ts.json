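{
  "id": "via_citrate_ts",
  "name": "Via citrate (tartronate semialdehyde route)",
  "oxygen_class": "anaerobic",
  "metabolites": [
    {
      "id": "AcCoA",
      "carbon": 2,
      "role": "internal"
    },
    {
      "id": "citrylCoA",
      "carbon": 6,
      "role": "internal"
    },
    {
      "id": "OAA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "glyoxylate",
      "carbon": 2,
      "role": "internal"
    },
    {
      "id": "succinylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "CO2",
      "carbon": 1,
      "role": "clamped"
    },
    {
      "id": "CoA",
      "carbon": 0,
      "role": "internal"
    },
    {
      "id": "H2",
      "carbon": 0,
      "role": "clamped"
    },
    {
      "id": "H2O",
      "carbon": 0,
      "role": "fixed_activity"
    },
    {
      "id": "KGA",
      "carbon": 5,
      "role": "internal"
    },
    {
      "id": "oxalosuccinate",
      "carbon": 6,
      "role": "internal"
    },
    {
      "id": "isocitrate",
      "carbon": 6,
      "role": "internal"
    },
    {
      "id": "cisaconitate",
      "carbon": 6,
      "role": "internal"
    },
    {
      "id": "citrate",
      "carbon": 6,
      "role": "internal"
    },
    {
      "id": "pyruvate",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "malate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "malylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "TSA",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "H+",
      "carbon": 0,
      "role": "fixed_activity"
    },
    {
      "id": "glycerate",
      "carbon": 3,
      "role": "internal"
    }
  ],
  "carriers": [
    {
      "id": "Fd",
      "E0_prime_V": -0.4,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    },
    {
      "id": "NAD",
      "E0_prime_V": -0.32,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    },
    {
      "id": "NADP",
      "E0_prime_V": -0.38,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    },
    {
      "id": "FAD",
      "E0_prime_V": -0.22,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    }
  ],
  "reactions": [
    {
      "id": "ccs",
      "stoich": {
        "AcCoA": -1,
        "citrylCoA": 1,
        "OAA": -1
      },
      "dG0_prime_kJ_mol": 0,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "cglyl",
      "stoich": {
        "citrylCoA": -1,
        "glyoxylate": 1,
        "succinylCoA": 1
      },
      "dG0_prime_kJ_mol": 5,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "kgs",
      "stoich": {
        "CO2": -1,
        "CoA": 1,
        "H2": -1,
        "H2O": 1,
        "KGA": 1,
        "succinylCoA": -1
      },
      "dG0_prime_kJ_mol": -13.5,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "Fd"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "kgc2",
      "stoich": {
        "CO2": -1,
        "KGA": -1,
        "oxalosuccinate": 1
      },
      "dG0_prime_kJ_mol": 5,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "idh2",
      "stoich": {
        "H2": -1,
        "isocitrate": 1,
        "oxalosuccinate": -1
      },
      "dG0_prime_kJ_mol": -35.2333,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "acn_a",
      "stoich": {
        "cisaconitate": 1,
        "H2O": 1,
        "isocitrate": -1
      },
      "dG0_prime_kJ_mol": 6,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "acn_b",
      "stoich": {
        "cisaconitate": -1,
        "citrate": 1,
        "H2O": -1
      },
      "dG0_prime_kJ_mol": -14,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "cl3",
      "stoich": {
        "AcCoA": 1,
        "citrate": -1,
        "CoA": -1,
        "OAA": 1
      },
      "dG0_prime_kJ_mol": -5,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "pfor2",
      "stoich": {
        "AcCoA": -1,
        "CO2": -1,
        "CoA": 1,
        "H2": -1,
        "H2O": 1,
        "pyruvate": 1
      },
      "dG0_prime_kJ_mol": 16.6,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "Fd",
          "NAD"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "me",
      "stoich": {
        "CO2": -1,
        "H2": -1,
        "malate": 1,
        "pyruvate": -1
      },
      "dG0_prime_kJ_mol": -30.2333,
      "slp_atp": 0,
      "cpt_capable": true,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD",
          "NADP",
          "FAD"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "mtk3",
      "stoich": {
        "CoA": -1,
        "malate": -1,
        "malylCoA": 1
      },
      "dG0_prime_kJ_mol": 35,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "mcl2",
      "stoich": {
        "AcCoA": 1,
        "glyoxylate": 1,
        "malylCoA": -1
      },
      "dG0_prime_kJ_mol": 5,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "tsa_s",
      "stoich": {
        "CO2": 1,
        "glyoxylate": -2,
        "TSA": 1,
        "H+": 1
      },
      "dG0_prime_kJ_mol": -20,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "tsa_r",
      "stoich": {
        "glycerate": 1,
        "H2": -1,
        "TSA": -1
      },
      "dG0_prime_kJ_mol": -35.2333,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD",
          "NADP"
        ],
        "direction": "reduction"
      }
    }
  ],
  "end_product": "glycerate",
  "overall": {
    "stoich": {
      "CO2": -3,
      "glycerate": 1,
      "H+": 1,
      "H2": -5,
      "H2O": 2
    },
    "dG0_prime_kJ_mol": -80.6
  },
  "declared": {
    "slp_cost": 2,
    "variants": 12,
    "reactions": 14
  }
}
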