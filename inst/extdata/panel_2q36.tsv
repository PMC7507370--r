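id	chrom	pos	ref	alt	pop_het
rs11674718	chr2	227300000	C	T	0.49
rs11899501	chr2	227650000	A	T	0.48
rs113504229	chr2	227980000	A	G	0.47
rs191358413	chr2	228240000	C	G	0.46
rs77356042	chr2	228690000	T	C	0.45
rs11681613	chr2	229020000	G	T	0.44
rs_far_up	chr2	222500000	A	C	0.50
rs_far_down	chr2	233900000	G	A	0.50
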