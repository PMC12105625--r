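compound,E_SMD_DFT,E_SMD_DFT_H2O,E_SMD_CBS,E_SMD_CBS_H2O,E_exp,pH,row_type
A,1.54,1.51,1.83,1.79,1.32,7.0,M1
T,1.91,1.81,2.15,2.05,1.29,7.0,M1
G,1.25,1.19,1.48,1.45,1.04,7.0,M1
C,1.75,1.72,1.91,1.89,1.44,7.0,M1
U,2.25,2.11,2.44,2.32,1.34,7.0,M1
1mG,1.20,1.18,1.43,1.44,1.06,7.0,M1
X,1.58,1.48,1.75,1.66,0.93,7.0,M2
hX,1.82,1.74,2.04,1.98,1.16,7.0,M2
hX,1.37,1.35,1.54,1.52,1.05,9.0,M2
1mInd,0.91,0.97,1.19,1.21,1.23,7.0,M1
Ind,1.03,0.99,1.33,1.30,1.24,7.0,M1
PhOH,1.57,1.32,1.84,1.64,1.35,7.0,M1
tAn,1.28,1.34,1.56,1.58,1.45,7.0,M1
Caf,1.54,1.59,1.79,1.81,1.50,7.0,M1
X,1.83,1.69,2.00,1.89,,,M1_neutral
d_X,0.81,0.78,0.94,0.92,,,M1_deprotonated
hX,1.83,1.75,2.05,1.99,,,M1_neutral
d_hX,1.00,1.04,1.14,1.14,,,M1_deprotonated
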