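block	gene	snp_id	wild_type	immune	note	AWK_fam3	AWL_fam185	BIR_fam237	BIP_fam114
recessive	AKNA	rs3748176	G	1			A/A	A/A	A/A
recessive	DNTTIP2	rs3747965	C	1			A/A	A/A	A/A
recessive	FRMD1	rs1548349	G	0			C/C	C/C	C/C
recessive	HJURP	rs3806589	T	0	two_cells_printed			C/C	C/C
recessive	HJURP	rs3732215	G	0			C/C	C/C	C/C
recessive	IFIH1	rs3747517	T	1			C/C	C/C	C/C
recessive	KLHL3	rs2905608	T	1			C/C	C/C	C/C
recessive	KNG1	rs710446	T	1			C/C	C/C	C/C
recessive	MIB2	rs7418389	T	1			C/C	C/C	C/C
recessive	MS4A14	rs3217518	ATT	1			A/A	A/A	A/A
recessive	RTP2	rs11707167	T	0			C/C	C/C	C/C
recessive	SLC22A16	rs714368	T	0			C/C	C/C	C/C
recessive	THSD7B	rs10206850	A	1			G/G	G/G	G/G
recessive	TMPRSS5	rs7110736	A	0			G/G	G/G	G/G
recessive	TSPAN8	rs3763978	C	0			G/G	G/G	G/G
dominant	ACBD3	novel	CTTTTTTTT	0	novel 1:g.226352490CTTTTTTTT>CTTTTTTT frameshift		CTTTTTTTT/CTTTTTTT	CTTTTTTTT/CTTTTTTT	CTTTTTTTT/CTTTTTTT
dominant	ALAD	rs1800435	C	1			C/G	C/G	C/G
dominant	APEX1	rs1130409	T	1			T/G	T/G	T/G
dominant	EGFL8	rs3096697	G	0			G/A	G/A	G/A
dominant	HSD17B4	rs25640	G	0			G/A	G/A	G/A
dominant	IQCG	rs9880989	G	0			G/T	G/T	G/T
dominant	KLC2	rs2276036	C	1			C/T	C/T	C/T
dominant	L3MBTL4	rs3737353	C	0			C/T	C/T	C/T
dominant	LIPK	rs1214464	G	0			G/C	G/C	G/C
dominant	LRCH4	novel	GTC	0	novel 7:g.100175472GTC>GC frameshift		GTC/GC	GTC/GC	GTC/GC
dominant	MKI67	rs8473	T	0			T/C	T/C	T/C
dominant	MKI67	rs11106	G	0			G/C	G/C	G/C
dominant	MS4A12	rs2298553	C	0			C/T	C/T	C/T
dominant	PCDH12	rs164515	C	0			C/T	C/T	C/T
dominant	PIK3AP1	rs17112076	C	1			C/T	C/T	C/T
dominant	PPT2	rs3096696	C	1	EVS		C/A	C/A	C/A
dominant	PRDM16	rs2493292	C	1			C/T	C/T	T/T
dominant	TBC1D26	rs11650318	C	0			C/T	C/T	C/T
dominant	TBC1D26	rs17855672	G	0			G/A	G/A	G/A
dominant	TRIM16	rs1060903	C	0			C/A	C/A	C/A
dominant	TSPYL1	rs3828743	G	0			G/A	G/A	G/A
dominant	VSTM4	rs13088	A	0			A/G	A/G	A/G
dominant	ZNF286A	rs3760299	T	0			T/C	T/C	T/C
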