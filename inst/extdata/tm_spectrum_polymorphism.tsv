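ref	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	0	0	0	0.12	0	0	0.31	0.43	0	0	0	0	0	0	0.74	1.05	5.54	0	0	4.06
R	0	0	0	0	0.49	0.55	0	0.25	0.37	0	0.18	0.06	0.12	0	0.18	0.06	0	0.31	0	0
N	0	0	0	0.25	0	0	0	0	0.06	0.25	0	0.31	0	0	0	0.62	0.06	0	0	0
D	0.06	0	0.25	0	0	0	0.12	0.12	0.12	0	0	0	0	0	0	0	0	0	0.06	0
C	0	0.55	0	0	0	0	0	0.31	0	0	0	0	0	0.12	0	0.43	0	0.43	0.55	0
Q	0	0.37	0	0	0	0	0	0	0.18	0	0	0	0	0	0	0	0	0	0	0
E	0.12	0	0	0.06	0	0.06	0	0	0	0	0	0.06	0	0	0	0	0	0	0	0.06
G	0.55	0.74	0	0.43	0.43	0	0.37	0	0	0	0	0	0	0	0	1.29	0	0.12	0	0.43
H	0	0.62	0.12	0	0	0.06	0	0	0	0	0	0	0	0	0	0	0	0	0	0
I	0	0	0.43	0	0	0	0	0	0	0	0.68	0	0.92	0.55	0	0.12	3.69	0	0	6.09
L	0	0.37	0	0	0	0.31	0	0	0.25	1.05	0	0	0.8	3.26	1.6	0.55	0	0.12	0	2.34
K	0	0.25	0.12	0	0	0	0	0	0	0	0	0	0.12	0	0	0	0	0	0	0
M	0	0.06	0	0	0	0	0	0	0	1.05	0.86	0.18	0	0	0	0	1.78	0	0	2.71
F	0	0	0	0	0.55	0	0	0	0	0.06	4.49	0	0	0	0	1.23	0	0	0.31	0.62
P	0.06	0.18	0	0	0	0.06	0	0	0.06	0	0.8	0	0	0	0	0.86	0.12	0	0	0
S	0.74	0.18	0.55	0	0.55	0	0	0.98	0	0.25	1.11	0	0	0.62	0.8	0	0.62	0.06	0.12	0
T	2.71	0.25	0.18	0	0	0	0	0	0	1.48	0	0.31	1.66	0	0.43	0.55	0	0	0	0
W	0	0.18	0	0	0.37	0	0	0.06	0	0	0.12	0	0	0	0	0.12	0	0	0	0
Y	0	0	0.06	0	1.35	0	0	0	0.74	0	0	0	0	0.18	0	0.18	0	0	0	0
V	1.78	0	0	0.18	0	0	0.25	0.8	0	7.01	2.28	0	4.37	0.55	0	0	0	0	0	0
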