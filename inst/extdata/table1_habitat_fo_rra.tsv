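category	phylum	DJ_FO	DJ_RRA	NDJ_FO	NDJ_RRA	QDH_FO	QDH_RRA	SKSK_FO	SKSK_RRA	XJ_FO	XJ_RRA
phytoplankton	Chlorophyta	60	25.89	100	85.47	100	32.98	100	2.74	100	24.42
phytoplankton	Bacillariophyta	60	3.37	20	0.42	100	24.91	100	63.16	40	0.84
protozoa	Ciliophora	20	0.21	80	3.58	0	0	100	14.32	100	17.05
protozoa	Microsporidia	20	4.42	0	0	0	0	0	0	0	0
protozoa	Cercozoa	0	0	80	1.89	0	0	20	0.21	0	0
protozoa	Picozoa	0	0	0	0	33.33	0.35	20	0.42	0	0
protozoa	Apicomplexa	40	0.63	20	0.21	0	0	20	0.21	20	0.42
zooplankton	Arthropoda	80	43.58	80	4.63	33.33	0.35	60	1.05	80	9.47
zooplankton	Rotifera	20	0.21	40	0.42	0	0	80	1.26	60	2.32
zooplankton	Cnidaria	0	0	0	0	0	0	20	1.26	20	0.21
zoobenthos	Bryozoa	0	0	0	0	33.33	0.70	20	10.11	0	0
zoobenthos	Annelida	0	0	0	0	66.67	2.46	20	0.21	0	0
zoobenthos	Nemertea	20	0.21	0	0	0	0	0	0	20	0.63
zoobenthos	Gastrotricha	0	0	0	0	0	0	0	0	20	0.42
zoobenthos	Nematoda	0	0	0	0	0	0	20	0.42	20	0.21
zoobenthos	Mollusca	0	0	0	0	0	0	20	0.21	0	0
detritus	Ascomycota	60	5.68	40	0.63	100	21.05	40	0.63	100	16.63
detritus	Streptophyta	60	2.32	20	0.42	33.33	4.91	0	0	60	4.00
detritus	Oomycota	0	0	20	0.21	0	0	20	0.21	40	1.89
detritus	Basidiomycota	20	0.42	0	0	33.33	0.70	0	0	80	1.68
detritus	Cryptomycota	40	1.05	40	0.63	33.33	1.05	20	0.21	40	0.84
detritus	Chytridiomycota	0	0	0	0	33.33	0.35	80	0.84	40	1.05
other	Unidentified	80	12.00	100	1.47	100	10.18	100	2.53	100	17.89
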