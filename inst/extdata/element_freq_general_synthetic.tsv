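element	frequency
C	0.620
N	0.120
O	0.150
S	0.030
Cl	0.025
F	0.020
P	0.015
Br	0.008
Si	0.004
Fe	0.0015
Cu	0.0015
Zn	0.0010
Ni	0.0010
Co	0.0008
Mn	0.0008
Cr	0.0005
Ti	0.0004
V	0.0003
Sc	0.0002
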