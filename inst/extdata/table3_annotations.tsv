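Chr	Start	Ref	Alt	Gene	Func	ExonicFunc	AAChange	dbSNP	gnomAD_WES_ALL	gnomAD_WES_SAS	gnomAD_WES_EAS	gnomAD_WGS_ALL	gnomAD_WGS_EAS	KG1000_ALL	KG1000_EAS	SIFT_score	Polyphen2_HVAR_score	CADD_phred	GERP_RS
chr3	145799628	T	A	PLOD2	exonic	nonsynonymous SNV	NM_182943:c.A1255T:p.Thr419Ser	rs776654051	3.99E-06	0	5.44E-05	.	.	.	.	0.88	0.515	10.78	5.53
chr11	118402939	G	A	TMEM25	exonic	nonsynonymous SNV	NM_032780:c.G145A:p.Ala49Thr	rs782188288	1.00E-04	1.00E-04	0.0013	.	.	.	.	0.55	0.209	15.48	3.26
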