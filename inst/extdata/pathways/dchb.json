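{
  "id": "dchb",
  "name": "Dicarboxylate hydroxybutyrate cycle",
  "oxygen_class": "anaerobic",
  "metabolites": [
    {
      "id": "AcCoA",
      "carbon": 2,
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
      "id": "pyruvate",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "PEP",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "HCO3",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "OAA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "malate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "fumarate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "succinate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "succinylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "SSA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "4HB",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "4HBCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "vinylacetylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "crotonylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "3HBCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "acetoacetylCoA",
      "carbon": 4,
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
    },
    {
      "id": "quinone",
      "E0_prime_V": -0.075,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    }
  ],
  "reactions": [
    {
      "id": "pfor",
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
      "id": "ppsk",
      "stoich": {
        "PEP": 1,
        "pyruvate": -1
      },
      "dG0_prime_kJ_mol": 39.35,
      "slp_atp": -2,
      "cpt_capable": false
    },
    {
      "id": "ca",
      "stoich": {
        "CO2": -1,
        "H2O": -1,
        "HCO3": 1
      },
      "dG0_prime_kJ_mol": -4,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "ppc",
      "stoich": {
        "H2O": 1,
        "HCO3": -1,
        "OAA": 1,
        "PEP": -1
      },
      "dG0_prime_kJ_mol": -30,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "mdh",
      "stoich": {
        "H2": -1,
        "malate": 1,
        "OAA": -1
      },
      "dG0_prime_kJ_mol": -47.9,
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
      "id": "fum_hyd",
      "stoich": {
        "fumarate": 1,
        "H2O": 1,
        "malate": -1
      },
      "dG0_prime_kJ_mol": 3.6,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "fum_red",
      "stoich": {
        "fumarate": -1,
        "H2": -1,
        "succinate": 1
      },
      "dG0_prime_kJ_mol": -85.9,
      "slp_atp": 0,
      "cpt_capable": true,
      "redox": {
        "n_e": 2,
        "carriers": [
          "quinone",
          "FAD",
          "NAD"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "scs",
      "stoich": {
        "CoA": -1,
        "succinate": -1,
        "succinylCoA": 1
      },
      "dG0_prime_kJ_mol": 35,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "ssadh",
      "stoich": {
        "CoA": 1,
        "H2": -1,
        "SSA": 1,
        "succinylCoA": -1
      },
      "dG0_prime_kJ_mol": -37.55,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NADP",
          "NAD"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "ssar",
      "stoich": {
        "4HB": 1,
        "H2": -1,
        "SSA": -1
      },
      "dG0_prime_kJ_mol": -47.55,
      "slp_atp": 0,
      "cpt_capable": true,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD",
          "NADP",
          "quinone"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "hbcl",
      "stoich": {
        "4HB": -1,
        "4HBCoA": 1,
        "CoA": -1
      },
      "dG0_prime_kJ_mol": 12.45,
      "slp_atp": -0.5,
      "cpt_capable": false
    },
    {
      "id": "hbd_a",
      "stoich": {
        "4HBCoA": -1,
        "H2O": 1,
        "vinylacetylCoA": 1
      },
      "dG0_prime_kJ_mol": 10,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "hbd_b",
      "stoich": {
        "crotonylCoA": 1,
        "vinylacetylCoA": -1
      },
      "dG0_prime_kJ_mol": -10,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "ech",
      "stoich": {
        "3HBCoA": 1,
        "crotonylCoA": -1,
        "H2O": -1
      },
      "dG0_prime_kJ_mol": -3,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "hbdh",
      "stoich": {
        "3HBCoA": -1,
        "acetoacetylCoA": 1,
        "H2": 1
      },
      "dG0_prime_kJ_mol": 31.6,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD",
          "NADP"
        ],
        "direction": "oxidation"
      }
    },
    {
      "id": "thl",
      "stoich": {
        "AcCoA": 2,
        "acetoacetylCoA": -1,
        "CoA": -1,
        "H2O": 1
      },
      "dG0_prime_kJ_mol": -25,
      "slp_atp": 0,
      "cpt_capable": false
    }
  ],
  "end_product": "AcCoA",
  "overall": {
    "stoich": {
      "AcCoA": 1,
      "CO2": -2,
      "CoA": -1,
      "H2": -4,
      "H2O": 3
    },
    "dG0_prime_kJ_mol": -142.3
  },
  "declared": {
    "slp_cost": 3.5,
    "variants": 216,
    "reactions": 16
  }
}
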