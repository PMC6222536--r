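residue	hydrophilicity	hydrophobicity	mass
A	-0.5	0.62	15
C	-1	0.29	47
D	3	-0.9	59
E	3	-0.74	73
F	-2.5	1.19	91
G	0	0.48	1
H	-0.5	-0.4	82
I	-1.8	1.38	57
K	3	-1.5	73
L	-1.8	1.06	57
M	-1.3	0.64	75
N	0.2	-0.78	58
P	0	0.12	42
Q	0.2	-0.85	72
R	3	-2.53	101
S	0.3	-0.18	31
T	-0.4	-0.05	45
V	-1.5	1.08	43
W	-3.4	0.81	130
Y	-2.3	0.26	107
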