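{
  "id": "via_malonyl_ts",
  "name": "Via malonyl-CoA (tartronate semialdehyde route)",
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
      "id": "MSA_hydrate",
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
      "id": "succinate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "fumarate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "malate",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "malylP",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "malylCoA",
      "carbon": 4,
      "role": "internal"
    },
    {
      "id": "glyoxylate",
      "carbon": 2,
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
      "id": "ca1",
      "stoich": {
        "CO2": -1,
        "H2O": -1,
        "HCO3": 1
      },
      "dG0_prime_kJ_mol": -4,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "ca2",
      "stoich": {
        "CO2": -1,
        "H2O": -1,
        "HCO3": 1
      },
      "dG0_prime_kJ_mol": -4,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "acc",
      "stoich": {
        "AcCoA": -1,
        "H2O": 1,
        "HCO3": -1,
        "malonylCoA": 1
      },
      "dG0_prime_kJ_mol": 13.075,
      "slp_atp": -1,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mcr1",
      "stoich": {
        "CoA": 1,
        "H2": -1,
        "malonylCoA": -1,
        "MSA": 1
      },
      "dG0_prime_kJ_mol": -21.925,
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
      "id": "msa_h",
      "stoich": {
        "H2O": -1,
        "MSA": -1,
        "MSA_hydrate": 1
      },
      "dG0_prime_kJ_mol": -1,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mcr2",
      "stoich": {
        "3HP": 1,
        "H2": -1,
        "H2O": 1,
        "MSA_hydrate": -1
      },
      "dG0_prime_kJ_mol": -35.925,
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
      "id": "pcs1",
      "stoich": {
        "3HP": -1,
        "3HPCoA": 1,
        "CoA": -1
      },
      "dG0_prime_kJ_mol": 35,
      "slp_atp": -1,
      "cpt_capable": false,
      "flux": 2
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
      "cpt_capable": false,
      "flux": 2
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
      "id": "pcc",
      "stoich": {
        "H2O": 1,
        "HCO3": -1,
        "MMCoA": 1,
        "propionylCoA": -1
      },
      "dG0_prime_kJ_mol": 13.075,
      "slp_atp": -1,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "epim",
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
      "id": "mcm",
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
      "id": "sch",
      "stoich": {
        "CoA": 1,
        "H2O": -1,
        "succinate": 1,
        "succinylCoA": -1
      },
      "dG0_prime_kJ_mol": -35,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "sdh_ox",
      "stoich": {
        "fumarate": 1,
        "H2": 1,
        "succinate": -1
      },
      "dG0_prime_kJ_mol": 85.9,
      "slp_atp": 0,
      "cpt_capable": true,
      "flux": 2,
      "redox": {
        "n_e": 2,
        "carriers": [
          "NAD"
        ],
        "direction": "oxidation"
      }
    },
    {
      "id": "fum_hyd",
      "stoich": {
        "fumarate": -1,
        "H2O": -1,
        "malate": 1
      },
      "dG0_prime_kJ_mol": -3.6,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mtk2a",
      "stoich": {
        "malate": -1,
        "malylP": 1
      },
      "dG0_prime_kJ_mol": 10,
      "slp_atp": -0.5,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mtk2b",
      "stoich": {
        "CoA": -1,
        "malylCoA": 1,
        "malylP": -1
      },
      "dG0_prime_kJ_mol": 5,
      "slp_atp": 0,
      "cpt_capable": false,
      "flux": 2
    },
    {
      "id": "mcl",
      "stoich": {
        "AcCoA": 1,
        "glyoxylate": 1,
        "malylCoA": -1
      },
      "dG0_prime_kJ_mol": 10,
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
        "H2O": 4,
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
    "slp_cost": 7,
    "variants": 4,
    "reactions": 20
  }
}
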