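##fileformat=VCFv4.2
##source=varcascade shipped example (published candidate-variant rows)
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by Depth">
##FILTER=<ID=PASS,Description="All filters passed">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	1-b	2-a	2-b
chr3	145799628	rs776654051	T	A	.	PASS	QD=25.1	GT	0/1	0/0	0/0
chr11	118402939	rs782188288	G	A	.	PASS	QD=27.4	GT	0/0	0/1	0/1
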