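element	radius
H	0.31
C	0.76
N	0.71
O	0.66
F	0.57
Si	1.11
P	1.07
S	1.05
Cl	1.02
Br	1.20
Sc	1.70
Ti	1.60
V	1.53
Cr	1.39
Mn	1.39
Fe	1.32
Co	1.26
Ni	1.24
Cu	1.32
Zn	1.22
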