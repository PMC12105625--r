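{
  "description": "Calculated absolute oxidation potentials in aqueous solution (V vs SHE) of cytosine and uracil epigenetic derivatives: standard M1 values and pH 7 M4 values, for four method columns (SMD/DFT and SMD/CBS, each without and with one explicit water molecule). 'd_' prefixes denote deprotonated forms (the deprotonated-pathway potential E(R.|R-)); '1m' denotes N1-methylation mimicking the glycosidic bond. The two experimental anchors (C 1.44, U 1.34) are pH 7 values.",
  "units": {"all_E_columns": "V vs SHE"},
  "numeric_columns": ["M1_SMD_DFT", "M1_SMD_DFT_H2O", "M1_SMD_CBS", "M1_SMD_CBS_H2O", "M4_SMD_DFT", "M4_SMD_DFT_H2O", "M4_SMD_CBS", "M4_SMD_CBS_H2O", "E_exp"],
  "censored_columns": []
}
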