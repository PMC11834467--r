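{
  "id": "wl_methanogenic",
  "name": "Methanogenic Wood-Ljungdahl pathway",
  "oxygen_class": "anaerobic",
  "metabolites": [
    {
      "id": "CO2",
      "carbon": 1,
      "role": "clamped"
    },
    {
      "id": "formylMFR",
      "carbon": 1,
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
      "id": "MFR",
      "carbon": 0,
      "role": "internal"
    },
    {
      "id": "formylH4MPT",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "H4MPT",
      "carbon": 0,
      "role": "internal"
    },
    {
      "id": "methenylH4MPT",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "methyleneH4MPT",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "methylH4MPT",
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
      "id": "Fd",
      "E0_prime_V": -0.4,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    },
    {
      "id": "F420",
      "E0_prime_V": -0.36,
      "electrons": 2,
      "ratio_bounds": [0.01, 100]
    }
  ],
  "reactions": [
    {
      "id": "fmd",
      "stoich": {
        "CO2": -1,
        "formylMFR": 1,
        "H2": -1,
        "H2O": 1,
        "MFR": -1
      },
      "dG0_prime_kJ_mol": 16,
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
      "id": "ftr",
      "stoich": {
        "formylH4MPT": 1,
        "formylMFR": -1,
        "H4MPT": -1,
        "MFR": 1
      },
      "dG0_prime_kJ_mol": -4.4,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "mch",
      "stoich": {
        "formylH4MPT": -1,
        "H2O": 1,
        "methenylH4MPT": 1
      },
      "dG0_prime_kJ_mol": -4.6,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "mtd",
      "stoich": {
        "H2": -1,
        "methenylH4MPT": -1,
        "methyleneH4MPT": 1
      },
      "dG0_prime_kJ_mol": -30,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "F420"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "mer",
      "stoich": {
        "H2": -1,
        "methyleneH4MPT": -1,
        "methylH4MPT": 1
      },
      "dG0_prime_kJ_mol": -40,
      "slp_atp": 0,
      "cpt_capable": false,
      "redox": {
        "n_e": 2,
        "carriers": [
          "F420"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "mtr",
      "stoich": {
        "CoFeSP": -1,
        "H4MPT": 1,
        "methylCoFeSP": 1,
        "methylH4MPT": -1
      },
      "dG0_prime_kJ_mol": -30,
      "slp_atp": 0,
      "cpt_capable": true
    },
    {
      "id": "codh",
      "stoich": {
        "CO": 1,
        "CO2": -1,
        "H2": -1,
        "H2O": 1
      },
      "dG0_prime_kJ_mol": 12,
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
      "id": "acs_a",
      "stoich": {
        "acetylCoFeSP": 1,
        "CO": -1,
        "methylCoFeSP": -1
      },
      "dG0_prime_kJ_mol": -41.3,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "acs_b",
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
    "slp_cost": 0,
    "variants": 1,
    "reactions": 9
  }
}
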