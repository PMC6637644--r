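NOD-like receptor signalling	innate immune sensing	CTSB	CARD17	VDAC1	VDAC2	GBP5	NAMPT	GBP4	GBP1
Platelet activation	hemostasis signalling	SYK	PLCB3	VAMP8	RASGRP2	GNAI3	SNAP23	LYN
Glycolysis gluconeogenesis	central carbon metabolism	PFKM	HK2	AKR1A1	ENO2	PCK2	ALDH1A3
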