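marker	father_a1	father_a2	mother_a1	mother_a2	child_a1	child_a2
D8S1179	13	17	13	13	13	17
D21S11	15	15	14	21	14	15
D7S820	12	9	6	10	10	9
CSF1PO	15	15	20	16	20	15
D3S1358	9	10	11	13	11	9
TH01	12	10	12	16	12	10
D13S317	12	13	19	17	19	12
D16S539	16	12	18	14	14	12
D2S1338	15	18	17	18	18	18
D19S433	14	8	9	14	9	14
vWA	10	7	7	11	11	7
TPOX	10	9	12	11	11	10
D18S51	19	15	15	21	15	19
Amel	X	Y	X	X	X	X
D5S818	14	15	12	11	12	15
FGA	15	12	14	14	14	12
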