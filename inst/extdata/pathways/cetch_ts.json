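{
  "id": "cetch_ts",
  "name": "CETCH cycle (tartronate semialdehyde route)",
  "oxygen_class": "aerobic",
  "metabolites": [
    {
      "id": "CO2",
      "carbon": 1,
      "role": "clamped"
    },
    {
      "id": "crotonylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "ethylmalonylCoA",
      "carbon": 5,
      "role": "internal"
    },
    {
      "id": "H2",
      "carbon": 0,
      "role": "clamped"
    },
    {
      "id": "ethylmalonylCoAr",
      "carbon": 5,
      "role": "internal"
    },
    {
      "id": "methylsuccinylCoA",
      "carbon": 5,
      "role": "internal"
    },
    {
      "id": "mesaconylC1CoA",
      "carbon": 5,
      "role": "internal"
    },
    {
      "id": "mesaconylC4CoA",
      "carbon": 5,
      "role": "internal"
    },
    {
      "id": "H2O",
      "carbon": 0,
      "role": "fixed_activity"
    },
    {
      "id": "methylmalylCoA",
      "carbon": 5,
      "role": "internal"
    },
    {
      "id": "glyoxylate",
      "carbon": 2,
      "role": "internal"
    },
    {
      "id": "propionylCoA",
      "carbon": 3,
      "role": "internal"
    },
    {
      "id": "HCO3",
      "carbon": 1,
      "role": "internal"
    },
    {
      "id": "MMCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "MMCoAr",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "succinylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "CoA",
      "carbon": 0,
      "role": "internal"
    },
    {
      "id": "SSA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "SSA_hydrate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "4HB",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "4HBP",
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
    }
  ],
  "reactions": [
    {
      "id": "ccr",
      "stoich": {
        "CO2": -1,
        "crotonylCoA": -1,
        "ethylmalonylCoA": 1,
        "H2": -1
      },
      "dG0_prime_kJ_mol": -28.575,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NADP"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "eep",
      "stoich": {
        "ethylmalonylCoA": -1,
        "ethylmalonylCoAr": 1
      },
      "dG0_prime_kJ_mol": 0,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "eem",
      "stoich": {
        "ethylmalonylCoAr": -1,
        "methylsuccinylCoA": 1
      },
      "dG0_prime_kJ_mol": -5,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "msd",
      "stoich": {
        "H2": 1,
        "mesaconylC1CoA": 1,
        "methylsuccinylCoA": -1
      },
      "dG0_prime_kJ_mol": 46.425,
      "slp_atp": 0,
      "cpt_capable": true,
      "flux": 2,
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
      "id": "mtc2",
      "stoich": {
        "mesaconylC1CoA": -1,
        "mesaconylC4CoA": 1
      },
      "dG0_prime_kJ_mol": 0,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mch",
      "stoich": {
        "H2O": -1,
        "mesaconylC4CoA": -1,
        "methylmalylCoA": 1
      },
      "dG0_prime_kJ_mol": -5,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mml",
      "stoich": {
        "glyoxylate": 1,
        "methylmalylCoA": -1,
        "propionylCoA": 1
      },
      "dG0_prime_kJ_mol": 15,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "ca3",
      "stoich": {
        "CO2": -1,
        "H2O": -1,
        "HCO3": 1
      },
      "dG0_prime_kJ_mol": -4,
      "slp_atp": -0.5,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "pcc2",
      "stoich": {
        "H2O": 1,
        "HCO3": -1,
        "MMCoA": 1,
        "propionylCoA": -1
      },
      "dG0_prime_kJ_mol": 20,
      "slp_atp": -1,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "epim2",
      "stoich": {
        "MMCoA": -1,
        "MMCoAr": 1
      },
      "dG0_prime_kJ_mol": 0,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mcm2",
      "stoich": {
        "MMCoAr": -1,
        "succinylCoA": 1
      },
      "dG0_prime_kJ_mol": -7,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "ssr",
      "stoich": {
        "CoA": 1,
        "H2": -1,
        "SSA": 1,
        "succinylCoA": -1
      },
      "dG0_prime_kJ_mol": -23.575,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2,
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
      "id": "ssa_h",
      "stoich": {
        "H2O": -1,
        "SSA": -1,
        "SSA_hydrate": 1
      },
      "dG0_prime_kJ_mol": -1,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "ssar2",
      "stoich": {
        "4HB": 1,
        "H2": -1,
        "H2O": 1,
        "SSA_hydrate": -1
      },
      "dG0_prime_kJ_mol": -32.575,
      "slp_atp": 0,
      "cpt_capable": true,
      "flux": 2,
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
      "id": "hbk",
      "stoich": {
        "4HB": -1,
        "4HBP": 1
      },
      "dG0_prime_kJ_mol": 20,
      "slp_atp": -1,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "hbt",
      "stoich": {
        "4HBCoA": 1,
        "4HBP": -1,
        "CoA": -1
      },
      "dG0_prime_kJ_mol": -10,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "hbd_a2",
      "stoich": {
        "4HBCoA": -1,
        "H2O": 1,
        "vinylacetylCoA": 1
      },
      "dG0_prime_kJ_mol": 10,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "hbd_b2",
      "stoich": {
        "crotonylCoA": 1,
        "vinylacetylCoA": -1
      },
      "dG0_prime_kJ_mol": -10,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "tsa_s",
      "stoich": {
        "CO2": 1,
        "glyoxylate": -2,
        "TSA": 1,
        "H2O": 2,
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
      "dG0_prime_kJ_mol": -30,
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
    "slp_cost": 5,
    "variants": 16,
    "reactions": 20
  }
}
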