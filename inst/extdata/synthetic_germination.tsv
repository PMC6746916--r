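genotype	background	treatment	replicate	germination_pct
Col-0	Col	Rp	1	97
Col-0	Col	Rp	2	98
Col-0	Col	Rp	3	99
Col-0	Col	FRp	1	2
Col-0	Col	FRp	2	4
Col-0	Col	FRp	3	3
phyB-9	Col	Rp	1	8
phyB-9	Col	Rp	2	10
phyB-9	Col	Rp	3	12
phyB-9	Col	FRp	1	1
phyB-9	Col	FRp	2	3
phyB-9	Col	FRp	3	2
Ler	Ler	Rp	1	75
Ler	Ler	Rp	2	78
Ler	Ler	Rp	3	81
Ler	Ler	FRp	1	3
Ler	Ler	FRp	2	5
Ler	Ler	FRp	3	4
phyB-5	Ler	Rp	1	29
phyB-5	Ler	Rp	2	32
phyB-5	Ler	Rp	3	35
phyB-5	Ler	FRp	1	2
phyB-5	Ler	FRp	2	4
phyB-5	Ler	FRp	3	3
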