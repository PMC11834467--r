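{
  "id": "hp4hb",
  "name": "Hydroxypropionate hydroxybutyrate cycle",
  "oxygen_class": "aerobic",
  "metabolites": [
    {
      "id": "CO2",
      "carbon": 1,
      "role": "clamped"
    },
    {
      "id": "H2O",
      "carbon": 0,
      "role": "fixed_activity"
    },
    {
      "id": "HCO3",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "AcCoA",
      "carbon": 2,
      "role": "internal"
    },
    {
      "id": "malonylCoA",
      "carbon": 3,
      "role": "internal"
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
      "id": "MSA",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "3HP",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "3HPCoA",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "acryloylCoA",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "propionylCoA",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "MMCoA",
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
      "id": "NADP",
      "E0_prime_V": -0.38,
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
      "id": "FAD",
      "E0_prime_V": -0.22,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    }
  ],
  "reactions": [
    {
      "id": "ca",
      "stoich": {
        "CO2": -2,
        "H2O": -2,
        "HCO3": 2
      },
      "dG0_prime_kJ_mol": -8,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "acc",
      "stoich": {
        "AcCoA": -1,
        "H2O": 1,
        "HCO3": -1,
        "malonylCoA": 1
      },
      "dG0_prime_kJ_mol": 20,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "mcr1",
      "stoich": {
        "CoA": 1,
        "H2": -1,
        "malonylCoA": -1,
        "MSA": 1
      },
      "dG0_prime_kJ_mol": -21.5,
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
      "id": "mcr2",
      "stoich": {
        "3HP": 1,
        "H2": -1,
        "MSA": -1
      },
      "dG0_prime_kJ_mol": -36.5,
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
      "id": "pcs1",
      "stoich": {
        "3HP": -1,
        "3HPCoA": 1,
        "CoA": -1
      },
      "dG0_prime_kJ_mol": 28.5,
      "slp_atp": -2,
      "cpt_capable": false
    },
    {
      "id": "pcs2",
      "stoich": {
        "3HPCoA": -1,
        "acryloylCoA": 1,
        "H2O": 1
      },
      "dG0_prime_kJ_mol": 5,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "pcs3",
      "stoich": {
        "acryloylCoA": -1,
        "H2": -1,
        "propionylCoA": 1
      },
      "dG0_prime_kJ_mol": -79.9,
      "slp_atp": 0,
      "cpt_capable": true,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NADP",
          "FAD"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "pcc",
      "stoich": {
        "H2O": 1,
        "HCO3": -1,
        "MMCoA": 1,
        "propionylCoA": -1
      },
      "dG0_prime_kJ_mol": 20,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "mcm",
      "stoich": {
        "MMCoA": -1,
        "succinylCoA": 1
      },
      "dG0_prime_kJ_mol": -7,
      "slp_atp": 0,
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
      "dG0_prime_kJ_mol": -35,
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
      "dG0_prime_kJ_mol": -45,
      "slp_atp": 0,
      "cpt_capable": true,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD",
          "NADP"
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
      "dG0_prime_kJ_mol": 30,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "hbd_a",
      "stoich": {
        "4HBCoA": -1,
        "H2O": 1,
        "vinylacetylCoA": 1
      },
      "dG0_prime_kJ_mol": 0,
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
          "NAD"
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
        "H2O": 2
      },
      "dG0_prime_kJ_mol": -31.5,
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
    "slp_cost": 5,
    "variants": 32,
    "reactions": 17
  }
}
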