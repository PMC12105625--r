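{
  "description": "Linearly adjusted M4 (pH 7) oxidation potentials in aqueous solution (V vs SHE): the absolute M4 values scaled by the benchmark regression slope 0.60 and anchored so cytosine lands on its experimental 1.44 V (cytosine series) and uracil on 1.34 V (uracil series). Anchor rows are bold in print and exact by construction.",
  "units": {"all_E_columns": "V vs SHE"},
  "numeric_columns": ["M4_SMD_DFT", "M4_SMD_DFT_H2O", "M4_SMD_CBS", "M4_SMD_CBS_H2O"],
  "censored_columns": [],
  "adjustment": {"slope_factor": 0.60, "anchors": {"cytosine_series": {"compound": "C", "E_exp": 1.44}, "uracil_series": {"compound": "U", "E_exp": 1.34}}}
}
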