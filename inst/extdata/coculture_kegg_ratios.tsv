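pathway	comparison	accession	gene_name	description	average_ratio
NOD-like receptor signalling pathway	KG1a H/M	P07858	CTSB	Cathepsin B	3.66
NOD-like receptor signalling pathway	KG1a H/M	Q5XLA6	CARD17	Caspase recruitment domain-containing protein 17	2.91
NOD-like receptor signalling pathway	KG1a H/M	P21796	VDAC1	Voltage-dependent anion-selective channel protein 1	2.51
NOD-like receptor signalling pathway	KG1a H/M	P45880	VDAC2	Voltage-dependent anion-selective channel protein 2	2.46
NOD-like receptor signalling pathway	KG1a H/M	Q96PP8	GBP5	Guanylate-binding protein 5	2.38
NOD-like receptor signalling pathway	KG1a H/M	P43490	NAMPT	Nicotinamide phosphoribosyltransferase	1.89
NOD-like receptor signalling pathway	KG1a H/M	Q96PP9	GBP4	Guanylate-binding protein 4	1.73
NOD-like receptor signalling pathway	KG1a H/M	P32455	GBP1	Guanylate-binding protein 1	1.60
Platelet activation	KG1a H/M	P43405	SYK	Tyrosine-protein kinase SYK	0.61
Platelet activation	KG1a H/M	Q01970	PLCB3	1-Phosphatidylinositol 4,5-bisphosphate phosphodiesterase beta-3	0.58
Platelet activation	KG1a H/M	Q9BV40	VAMP8	Vesicle-associated membrane protein 8	0.56
Platelet activation	KG1a H/M	Q7LDG7	RASGRP2	Calcium and DAG-regulated guanine nucleotide exchange factor I	0.56
Platelet activation	KG1a H/M	P08754	GNAI3	Guanine nucleotide-binding protein G(k) subunit alpha	0.54
Platelet activation	KG1a H/M	O00161	SNAP23	Synaptosomal-associated protein 23	0.49
Platelet activation	KG1a H/M	P07948	LYN	Tyrosine-protein kinase Lyn	0.30
Glycolysis/gluconeogenesis	HS5 H/L	P08237	PFKM	ATP-dependent 6-phosphofructokinase, muscle type	0.62
Glycolysis/gluconeogenesis	HS5 H/L	P52789	HK2	Hexokinase-2	2.37
Glycolysis/gluconeogenesis	HS5 H/L	P14550	AKR1A1	Alcohol dehydrogenase [NADP(+)]	2.83
Glycolysis/gluconeogenesis	HS5 H/L	P09104	ENO2	Gamma-enolase	0.46
Glycolysis/gluconeogenesis	HS5 H/L	Q16822	PCK2	Phosphoenolpyruvate carboxykinase [GTP], mitochondrial	1.74
Glycolysis/gluconeogenesis	HS5 H/L	P47895	ALDH1A3	Aldehyde dehydrogenase family 1 member A3	0.36
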