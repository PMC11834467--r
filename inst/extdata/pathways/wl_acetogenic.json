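{
  "id": "wl_acetogenic",
  "name": "Acetogenic Wood-Ljungdahl pathway",
  "oxygen_class": "anaerobic",
  "metabolites": [
    {
      "id": "CO2",
      "carbon": 1,
      "role": "clamped"
    },
    {
      "id": "formate",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "H2",
      "carbon": 0,
      "role": "clamped"
    },
    {
      "id": "formylH4F",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "H2O",
      "carbon": 0,
      "role": "fixed_activity"
    },
    {
      "id": "H4F",
      "carbon": 0,
      "role": "internal"
    },
    {
      "id": "methenylH4F",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "methyleneH4F",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "methylH4F",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "CoFeSP",
      "carbon": 0,
      "role": "internal"
    },
    {
      "id": "methylCoFeSP",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "CO",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "acetylCoFeSP",
      "carbon": 2,
      "role": "internal"
    },
    {
      "id": "AcCoA",
      "carbon": 2,
      "role": "internal"
    },
    {
      "id": "CoA",
      "carbon": 0,
      "role": "internal"
    }
  ],
  "carriers": [
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
      "id": "Fd",
      "E0_prime_V": -0.4,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    }
  ],
  "reactions": [
    {
      "id": "fdh",
      "stoich": {
        "CO2": -1,
        "formate": 1,
        "H2": -1
      },
      "dG0_prime_kJ_mol": 1.2,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD",
          "NADP",
          "Fd"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "fhs",
      "stoich": {
        "formate": -1,
        "formylH4F": 1,
        "H2O": 1,
        "H4F": -1
      },
      "dG0_prime_kJ_mol": 25,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "mtc",
      "stoich": {
        "formylH4F": -1,
        "H2O": 1,
        "methenylH4F": 1
      },
      "dG0_prime_kJ_mol": -2,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "mtd2",
      "stoich": {
        "H2": -1,
        "methenylH4F": -1,
        "methyleneH4F": 1
      },
      "dG0_prime_kJ_mol": -22,
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
    },
    {
      "id": "mtr2",
      "stoich": {
        "H2": -1,
        "methyleneH4F": -1,
        "methylH4F": 1
      },
      "dG0_prime_kJ_mol": -41.3,
      "slp_atp": 0,
      "cpt_capable": true,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD",
          "Fd"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "mtrs",
      "stoich": {
        "CoFeSP": -1,
        "H4F": 1,
        "methylCoFeSP": 1,
        "methylH4F": -1
      },
      "dG0_prime_kJ_mol": -35,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "codh2",
      "stoich": {
        "CO": 1,
        "CO2": -1,
        "H2": -1,
        "H2O": 1
      },
      "dG0_prime_kJ_mol": 12,
      "slp_atp": 0,
      "cpt_capable": true,
      "redox": {
        "n_e": 2,
        "carriers": [
          "Fd"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "acs_a2",
      "stoich": {
        "acetylCoFeSP": 1,
        "CO": -1,
        "methylCoFeSP": -1
      },
      "dG0_prime_kJ_mol": -60.2,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "acs_b2",
      "stoich": {
        "AcCoA": 1,
        "acetylCoFeSP": -1,
        "CoA": -1,
        "CoFeSP": 1
      },
      "dG0_prime_kJ_mol": -20,
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
    "slp_cost": 1,
    "variants": 12,
    "reactions": 9
  }
}
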