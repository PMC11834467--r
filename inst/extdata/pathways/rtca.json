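{
  "id": "rtca",
  "name": "Reverse TCA cycle",
  "oxygen_class": "anaerobic",
  "metabolites": [
    {
      "id": "citrate",
      "carbon": 6,
      "role": "internal"
    },
    {
      "id": "citrylCoA",
      "carbon": 6,
      "role": "internal"
    },
    {
      "id": "CoA",
      "carbon": 0,
      "role": "internal"
    },
    {
      "id": "H2O",
      "carbon": 0,
      "role": "fixed_activity"
    },
    {
      "id": "AcCoA",
      "carbon": 2,
      "role": "internal"
    },
    {
      "id": "OAA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "H2",
      "carbon": 0,
      "role": "clamped"
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
      "id": "CO2",
      "carbon": 1,
      "role": "clamped"
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
      "id": "ccl1",
      "stoich": {
        "citrate": -1,
        "citrylCoA": 1,
        "CoA": -1,
        "H2O": 1
      },
      "dG0_prime_kJ_mol": 35,
      "slp_atp": -1,
      "cpt_capable": false
    },
    {
      "id": "ccl2",
      "stoich": {
        "AcCoA": 1,
        "citrylCoA": -1,
        "OAA": 1
      },
      "dG0_prime_kJ_mol": 5,
      "slp_atp": 0,
      "cpt_capable": false
    },
    {
      "id": "oaa_red",
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
      "id": "kga_synth",
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
          "Fd",
          "NAD"
        ],
        "direction": "reduction"
      }
    },
    {
      "id": "kga_carbox",
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
      "id": "oxs_red",
      "stoich": {
        "H2": -1,
        "isocitrate": 1,
        "oxalosuccinate": -1
      },
      "dG0_prime_kJ_mol": -70.6,
      "slp_atp": 0,
      "cpt_capable": true,
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
    "slp_cost": 2,
    "variants": 54,
    "reactions": 11
  }
}
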