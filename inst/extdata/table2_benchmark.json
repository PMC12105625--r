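{
  "description": "Gas-phase adiabatic ionization energies (M1, eV) and acetonitrile oxidation potentials (M1, V vs SCE) at the DFT and DLPNO-CCSD(T)/CBS levels, against experiment. The uracil acetonitrile experiment is a lower bound (>2.15 V). The printed AIE experiment for U (8.68 eV) differs from the 9.32 eV listed in the experimental-reference table; both are transcribed as printed.",
  "units": {"AIE_DFT": "eV", "AIE_CBS": "eV", "AIE_exp": "eV", "Eac_SMD_DFT": "V vs SCE", "Eac_SMD_CBS": "V vs SCE", "Eac_exp": "V vs SCE"},
  "numeric_columns": ["AIE_DFT", "AIE_CBS", "AIE_exp", "Eac_SMD_DFT", "Eac_SMD_CBS", "Eac_exp"],
  "censored_columns": ["Eac_exp"],
  "printed_metrics": {
    "AIE_DFT": {"r_squared": 0.98, "slope": 0.97, "intercept": 0.45, "mse": -0.25, "mue": 0.25, "rmse": 0.26},
    "AIE_CBS": {"r_squared": 0.99, "slope": 1.02, "intercept": -0.23, "mse": 0.03, "mue": 0.04, "rmse": 0.06},
    "Eac_SMD_DFT": {"r_squared": 0.98, "slope": 0.95, "intercept": 0.32, "mse": -0.26, "mue": 0.26, "rmse": 0.27},
    "Eac_SMD_CBS": {"r_squared": 0.96, "slope": 1.02, "intercept": -0.02, "mse": -0.01, "mue": 0.05, "rmse": 0.08}
  }
}
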