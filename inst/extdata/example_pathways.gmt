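hsa04726	serotonergic synapse (synthetic toy)	PGH2	GNAS	MAPK1	MAPK3	PRKCA	MAOA
hsa04915	oestrogen signalling (synthetic toy)	GNAS	MAPK1	MAPK3	PRKCA	NR3C1
hsa00053	ascorbate and aldarate metabolism (synthetic toy)	UGT1A1	UGT2B7	ALDH2
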