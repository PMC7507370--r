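##fileformat=VCFv4.2
##source=microseqr synthetic worked-example fixture (genotypes constructed, not transcribed)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	FATHER	MOTHER	PROBAND
chr2	222500000	rs_far_up	A	C	.	.	.	GT	0/1	0/0	0/0
chr2	227300000	rs11674718	C	T	.	.	.	GT	0/1	0/0	0/1
chr2	227650000	rs11899501	A	T	.	.	.	GT	0/1	0/0	0/1
chr2	227980000	rs113504229	A	G	.	.	.	GT	0/1	0/0	0/1
chr2	228100000	c.1322delT	AT	A	.	.	.	GT	0/0	0/1	0/1
chr2	228160000	c.2939T>A	T	A	.	.	.	GT	0/0	0/0	0/1
chr2	228240000	rs191358413	C	G	.	.	.	GT	0/1	0/0	0/1
chr2	228690000	rs77356042	T	C	.	.	.	GT	0/1	1/1	0/1
chr2	229020000	rs11681613	G	T	.	.	.	GT	0/1	0/0	0/1
chr2	233900000	rs_far_down	G	A	.	.	.	GT	0/0	0/1	0/1
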