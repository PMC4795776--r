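ref	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	0	0	0	1.39	0	0	0.98	0.46	0	0.05	0	0	0	0	1.19	0.26	2.53	0	0	2.68
R	0	0	0	0	1.08	1.14	0.05	0.15	1.39	0	0.36	0	0.05	0	0.36	0.26	0	0.83	0	0
N	0	0	0	0.62	0	0	0	0	0.1	0.36	0	0.72	0	0	0	0.77	0.15	0	0.21	0
D	0	0	0.88	0	0	0	0.15	0.26	0.15	0	0	0	0	0	0	0	0	0	0.67	0.21
C	0	1.65	0	0	0	0	0	0.15	0	0	0	0	0	0.15	0	0.21	0	0.26	0.98	0
Q	0	0.36	0	0	0	0	0.05	0	0.15	0	0.1	0.15	0	0	0.21	0	0	0	0	0
E	0	0	0	0.1	0	0.05	0	0.36	0	0	0	0.93	0	0	0	0	0	0	0	0
G	0.72	6.91	0	2.63	0.41	0	1.7	0	0	0	0.05	0.05	0	0	0	1.7	0	0.26	0	1.91
H	0	0.77	0.05	0.05	0	0.21	0	0	0	0	0.05	0	0	0	0.21	0	0	0	0.46	0
I	0	0.21	0.83	0	0	0	0	0	0	0	0.26	0.31	0.41	0.72	0	0.31	0.62	0	0	0.67
L	0	1.81	0	0	0	0.26	0	0	0.46	0.21	0	0	0.15	1.14	5.47	0.46	0	0.26	0	0.88
K	0	0	0.1	0	0	0	0.1	0	0	0	0	0	0	0	0	0	0.1	0	0	0
M	0	0.67	0	0	0	0	0	0	0	1.03	0.31	0.83	0	0	0	0	0.98	0	0	1.08
F	0	0	0	0	0.46	0	0	0	0	0.1	1.81	0	0	0	0	1.14	0.05	0	0.05	0.36
P	0.21	0.72	0	0	0	0.15	0	0	0.1	0	1.81	0	0	0	0	1.08	0.1	0	0	0
S	0	1.34	0.67	0	0.36	0	0	0.1	0	0.57	1.29	0	0	1.55	1.14	0	0.1	0.36	0.57	0
T	0.46	1.14	0.41	0	0	0	0	0	0	0.98	0	0.46	1.65	0	0.52	0.15	0	0	0	0
W	0	1.19	0	0	0.72	0	0	0.05	0	0	0.21	0	0	0	0	0.41	0	0	0	0
Y	0	0	0.1	0.15	1.6	0	0	0	0.62	0	0	0	0	0	0	0.36	0	0	0	0
V	0.72	0	0	0.62	0	0	0.41	0.31	0	1.7	0.57	0	2.06	1.03	0	0	0	0	0	0
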