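category	phylum	Spring_FO	Spring_RRA	Summer_FO	Summer_RRA	Autumn_FO	Autumn_RRA	Winter_FO	Winter_RRA
phytoplankton	Chlorophyta	80	2.013	100	3.30	86.67	2.96	93.33	1.35
phytoplankton	Bacillariophyta	86.67	22.89	73.33	0.48	73.33	0.26	93.33	9.42
phytoplankton	Haptophyta	33.33	0.021	13.33	0.015	0	0	0	0
protozoa	Ciliophora	93.33	15.71	100	27.27	100	45.36	100	28.0026
protozoa	Microsporidia	0	0	13.33	0.013	0	0	0	0
protozoa	Cercozoa	73.33	0.97	73.33	0.45	80	1.92	86.67	0.88
protozoa	Apicomplexa	53.33	0.13	73.33	0.77	66.67	0.43	46.67	0.046
protozoa	Picozoa	26.67	0.028	0	0	0	0	0	0
protozoa	Euglenozoa	26.67	0.21	40	1.39	13.33	0.023	26.67	0.041
protozoa	Imbricatea	26.67	0.19	0	0	0	0	6.67	0.010
protozoa	Heterolobosea	20	0.031	33.33	0.36	6.67	0.0051	0	0
protozoa	Endomyxa	33.33	0.20	0	0	0	0	0	0
protozoa	Tubulinea	40	0.21	33.33	0.064	13.33	0.0077	6.67	0.013
protozoa	Perkinsozoa	46.67	0.067	20	0.021	53.33	0.20	13.33	0.013
protozoa	Foraminifera	20	0.026	0	0	0	0	0	0
protozoa	Evosea	13.33	0.021	20	0.010	0	0	0	0
protozoa	Discosea	13.33	0.018	0	0	0	0	6.67	0.0077
zooplankton	Arthropoda	80	5.73	66.67	1.29	86.67	8.018	80	1.82
zooplankton	Rotifera	73.33	1.36	66.67	4.74	100	8.96	93.33	5.99
zooplankton	Cnidaria	86.67	1.37	40	0.26	26.67	0.090	60	1.76
zoobenthos	Bryozoa	40	3.52	33.33	0.41	13.33	0.018	46.67	0.77
zoobenthos	Annelida	80	7.36	100	26.041	93.33	8.018	86.67	18.054
zoobenthos	Nematoda	33.33	0.25	53.33	0.46	60	1.35	53.33	0.085
zoobenthos	Gastrotricha	40	0.082	33.33	0.031	6.67	0.0026	33.33	0.049
zoobenthos	Mollusca	66.67	0.60	100	5.80	93.33	3.073	33.33	4.59
zoobenthos	Platyhelminthes	60	0.34	80	1.90	60	1.28	86.67	1.11
zoobenthos	Tardigrada	26.67	0.031	20	0.17	6.67	0.0051	13.33	0.010
zoobenthos	Porifera	6.67	0.0026	6.67	0.0077	33.33	0.077	33.33	0.18
detritus	Streptophyta	80	4.76	86.67	8.062	80	2.046	53.33	2.76
detritus	Ascomycota	93.33	12.73	86.67	3.32	66.67	0.33	60	15.46
detritus	Oomycota	66.67	1.055	66.67	0.34	46.67	0.41	53.33	0.21
detritus	Basidiomycota	60	0.74	73.33	2.098	60	0.30	33.33	0.059
detritus	Cryptomycota	73.33	0.36	93.33	1.32	80	3.53	80	0.52
detritus	Chytridiomycota	80	0.79	80	0.21	60	0.17	80	0.14
detritus	Mucoromycota	46.67	0.27	33.33	0.13	46.67	0.077	40	0.12
detritus	Blastocladiomycota	20	0.021	13.33	0.010	6.67	0.12	0	0
detritus	Zoopagomycota	0	0	0	0	6.67	0.0051	0	0
other	Unidentified	100	15.93	100	9.26	100	10.94	100	6.53
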