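M00095	Mevalonate pathway (synthetic stand-in, non-authoritative)	ACAT1	ACAT2	HMGCS1	HMGCR	MVK	PMVK	MVD
map00900	Terpenoid backbone biosynthesis (synthetic stand-in, non-authoritative)	FDPS	GGPS1	IDI1	IDI2	DHDDS
H01593	Osteoporosis disease pathway (synthetic stand-in, non-authoritative)	LRP5	COL1A1	ESR1	VDR	TNFRSF11B	SOST
hsa04380	Osteoclast differentiation (synthetic stand-in, non-authoritative)	TRAF2	TRAF6	TNFSF11	TNFRSF11A	CSF1	CSF1R	NFATC1	FOS	JUN
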