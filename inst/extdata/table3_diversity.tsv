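index	unit	grouping	mean	se	letters
H	DJ	habitat	3.11	0.83	bc
H	NDJ	habitat	4.85	0.060	a
H	QDH	habitat	2.68	0.71	b
H	SKSK	habitat	2.50	0.24	b
H	XJ	habitat	4.53	0.21	ac
H	Spring	season	3.81	0.33
H	Summer	season	4.22	0.30
H	Autumn	season	4.11	0.21
H	Winter	season	4.18	0.27
J	DJ	habitat	0.71	0.10	bc
J	NDJ	habitat	0.90	0.0046	ac
J	QDH	habitat	0.57	0.11	b
J	SKSK	habitat	0.55	0.042	b
J	XJ	habitat	0.90	0.020	a
J	Spring	season	0.54	0.037
J	Summer	season	0.61	0.032
J	Autumn	season	0.61	0.021
J	Winter	season	0.60	0.031
B	DJ	habitat	2.28	0.56	a
B	NDJ	habitat	1.37	0.091	a
B	QDH	habitat	1.94	0.40	a
B	SKSK	habitat	2.026	0.34	a
B	XJ	habitat	4.25	0.49	b
B	Spring	season	2.99	0.47
B	Summer	season	3.45	0.47
B	Autumn	season	3.065	0.41
B	Winter	season	2.65	0.31
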