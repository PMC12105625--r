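{
  "description": "Experimental oxidation potentials in aqueous and acetonitrile solution, gas-phase adiabatic ionization energies, and aqueous pKa ladders for the benchmark compounds. Where the literature lists two aqueous values per compound, the pH 7 cyclic-voltammetry value is kept; the pH column gives the measurement pH. pKa columns are tagged by the charge q of the deprotonating acid: q=+1 the protonated reduced form, q=0 the neutral reduced molecule, q=-1 the reduced anion.",
  "units": {"AIE_eV": "eV", "Eox_acetonitrile_V": "V vs SCE", "Eox_aqueous_V": "V vs SHE", "pH": "unitless", "pKa_plus1_reduced": "unitless", "pKa_zero_reduced": "unitless", "pKa_minus1_reduced": "unitless"},
  "numeric_columns": ["AIE_eV", "Eox_acetonitrile_V", "Eox_aqueous_V", "pH", "pKa_plus1_reduced", "pKa_zero_reduced", "pKa_minus1_reduced"],
  "censored_columns": ["Eox_acetonitrile_V", "pKa_minus1_reduced"],
  "footnotes": {
    "hypoxanthine_pH9": "hX also measured at pH 9: 1.05 V",
    "caffeine": "caffeine has no acidic protons; its pKa(+1) refers to the protonated form"
  }
}
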