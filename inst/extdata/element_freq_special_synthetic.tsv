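element	frequency
C	0.250
N	0.090
O	0.150
S	0.030
Cl	0.020
Br	0.010
P	0.005
F	0.003
Si	0.002
Cu	0.080
Fe	0.070
Zn	0.060
Ni	0.060
Co	0.050
Mn	0.040
Cr	0.030
Ti	0.020
V	0.020
Sc	0.010
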