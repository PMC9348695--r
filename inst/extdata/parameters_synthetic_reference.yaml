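k_MONO: 1.0
d_MONO_B: 1.0
a: 0.590522049
alpha: 0.155300064
epsilon: 0.3667997069
c: 0.1008016358
b: 0.1710619631
k_LDL: 0.1812586163
f: 0.339379935
e: 0.05075306111
d_LDL: 0.1695164082
d_F: 0.007843951994
xi: 1.219821341
d_L_B: 1.0
R0: 0.9996
MONO_B_nor: 430.0
L_B_nor: 430.0
init_MONO: 0.0001
init_IM: 0.0001
init_L: 0.0001
init_F: 0.0001
d_HFD: 1.549120344
d_ABIO: 2.605936884
d_Immod: 2.735203843
d_PA: 0.7838942015
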