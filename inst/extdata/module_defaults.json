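{
  "version": "1.0",
  "expression_defaults": {
    "k_tx": 0.005,
    "k_tl": 0.0204,
    "delta_m": 0.005,
    "k_deg": 0.000385081766977747
  },
  "bursting_defaults": {
    "k_goff": 0.0028,
    "k_gon": 0.00045,
    "enabled": true
  },
  "expression_presets": {
    "low": 53,
    "mid": 529,
    "high": 5285
  },
  "module_defaults": {
    "linear_pathway": {
      "S": 1000,
      "k_cat1": 0.02,
      "K_m1": 100,
      "k_cat2": 0.0227,
      "K_m2": 25,
      "k_out": 0.01
    },
    "redundant_enzymes": {
      "S": 1000,
      "k_cat1": 0.01,
      "K_m1": 100,
      "k_cat2": 0.01,
      "K_m2": 100,
      "k_out": 0.005
    },
    "branch_point": {
      "J": 1.5,
      "k_cat1": 0.0236,
      "K_m1": 20,
      "k_cat2": 0.0236,
      "K_m2": 20,
      "k_out": 0.01
    },
    "dual_regulators_or": {
      "V_max": 0.01,
      "K": 53,
      "n": 2,
      "delta_mp": 0.005,
      "k_tl_p": 0.02,
      "k_deg_p": 0.000385081766977747
    },
    "physical_interaction": {
      "k_b": 0.01,
      "k_unb": 0.001
    },
    "covalent_modification": {
      "k_p": 0.002,
      "k_demod": 0.02,
      "k_cat_p": 0.0094,
      "K_p": 5,
      "V_d": 0.5,
      "K_d": 5
    },
    "lac_reduced": {
      "L_ext": 50000,
      "k_cat_y": 0.05,
      "K_m_y": 50000,
      "k_cat_z1": 0.1,
      "K_m_z1": 500,
      "k_cat_z2": 0.1,
      "K_m_z2": 500,
      "k_out": 0.01,
      "R_tot": 10,
      "k_ra": 0.001,
      "k_rd": 0.1,
      "K_R": 2,
      "n_R": 2
    }
  }
}
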