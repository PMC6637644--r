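Majority protein IDs	Gene names	Protein names	Ratio H/M normalized	Ratio H/M	Ratio H/L normalized	Ratio H/L	Potential contaminant	Reverse
P07858	CTSB	Cathepsin B	3.66	3.58	1.02	1.01
Q5XLA6	CARD17	Caspase recruitment domain-containing protein 17	2.91	2.88	0.98	0.97
P43405	SYK	Tyrosine-protein kinase SYK	0.61	0.62	1.05	1.06
P07948	LYN	Tyrosine-protein kinase Lyn	0.30	0.31	0.99	0.98
P21796;P45880	VDAC1	Voltage-dependent anion-selective channel protein 1	2.51	2.47	1.01	1.00
Q9BV40	VAMP8	Vesicle-associated membrane protein 8	0.56	0.57	1.03	1.02
P00000	KRT1	Keratin, type II cytoskeletal 1	1.12	1.10	1.00	1.00	+
REV__P11111	FAKE1	Reversed decoy	0.95	0.94	1.00	1.00		+
P99999	NOQUANT	Protein without quantification	NaN		1.00	1.00
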