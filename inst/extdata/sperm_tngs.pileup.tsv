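sample	chrom	pos	ref	alt	depth	alt_count
father_blood	chr2	228160000	T	A	10000	0
father_sperm	chr2	228160000	T	A	10000	265
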