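{
  "description": "Aqueous-solution oxidation potentials (V vs SHE), M1 for most compounds and Henderson-Hasselbalch-averaged M2 for the acidic xanthine/hypoxanthine rows (row_type M2, bold in print). The trailing M1_neutral/M1_deprotonated rows are the raw pathway components entering the M2 average. Method columns: SMD/DFT and SMD/CBS, each without and with one explicit water molecule.",
  "units": {"E_SMD_DFT": "V vs SHE", "E_SMD_DFT_H2O": "V vs SHE", "E_SMD_CBS": "V vs SHE", "E_SMD_CBS_H2O": "V vs SHE", "E_exp": "V vs SHE", "pH": "unitless"},
  "numeric_columns": ["E_SMD_DFT", "E_SMD_DFT_H2O", "E_SMD_CBS", "E_SMD_CBS_H2O", "E_exp", "pH"],
  "censored_columns": [],
  "mole_fractions": {
    "X_pH7": {"x_neutral": 0.76, "x_deprotonated": 0.24},
    "hX_pH7": {"x_neutral": 0.99, "x_deprotonated": 0.01},
    "hX_pH9": {"x_neutral": 0.44, "x_deprotonated": 0.56}
  },
  "printed_metrics": {
    "E_SMD_DFT": {"r_squared": 0.02, "slope": 0.06, "intercept": 1.17, "mse": 0.27, "mue": 0.38, "rmse": 0.47},
    "E_SMD_DFT_H2O": {"r_squared": 0.04, "slope": 0.10, "intercept": 1.11, "mse": 0.22, "mue": 0.32, "rmse": 0.41},
    "E_SMD_CBS": {"r_squared": 0.02, "slope": 0.08, "intercept": 1.12, "mse": 0.51, "mue": 0.52, "rmse": 0.63},
    "E_SMD_CBS_H2O": {"r_squared": 0.05, "slope": 0.11, "intercept": 1.07, "mse": 0.48, "mue": 0.48, "rmse": 0.58}
  }
}
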