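fragment_id	cell_id	site_id	observed_allele
1-1	1	.	.
1-2	1	.	.
2-1	2	rs11674718	T
2-1	2	rs11899501	T
2-1	2	rs113504229	G
2-1	2	rs191358413	G
2-1	2	rs77356042	T
2-1	2	rs11681613	T
2-1	2	c.2939T>A	A
2-2	2	.	.
3-1	3	.	.
3-2	3	.	.
4-1	4	.	.
4-2	4	.	.
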