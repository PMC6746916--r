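gene	genotype	treatment	replicate	iso_long	iso_short
U2AF65A	Col-0	Rp	1	420	580
U2AF65A	Col-0	Rp	2	400	610
U2AF65A	Col-0	Rp	3	440	570
U2AF65A	Col-0	FRp	1	630	370
U2AF65A	Col-0	FRp	2	610	400
U2AF65A	Col-0	FRp	3	650	360
U2AF65A	phyB-9	Rp	1	600	400
U2AF65A	phyB-9	Rp	2	580	430
U2AF65A	phyB-9	Rp	3	620	390
U2AF65A	phyB-9	FRp	1	610	390
U2AF65A	phyB-9	FRp	2	590	420
U2AF65A	phyB-9	FRp	3	630	380
SR30	Col-0	Rp	1	220	780
SR30	Col-0	Rp	2	240	760
SR30	Col-0	Rp	3	200	800
SR30	Col-0	FRp	1	560	440
SR30	Col-0	FRp	2	540	470
SR30	Col-0	FRp	3	580	420
SR30	phyB-9	Rp	1	230	770
SR30	phyB-9	Rp	2	250	750
SR30	phyB-9	Rp	3	210	790
SR30	phyB-9	FRp	1	550	450
SR30	phyB-9	FRp	2	530	480
SR30	phyB-9	FRp	3	570	430
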