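block	gene	snp_id	wild_type	immune	note	AWK_fam3	AWL_fam185	BIR_fam237	BIP_fam114
recessive	AAK1	rs66931661	CTGT	0			C/C	C/C	C/C
recessive	ABCB11	rs2287622	A	0			G/G	G/G	G/G
recessive	ALG1L	rs3828357	T	0			C/C	C/C	C/C
recessive	C1orf227	rs10864004	A	0			G/G	G/G	G/G
recessive	CD5	rs2229177	C	1			T/T	T/T	T/T
recessive	CPB2	rs1926447	A	1			G/G	G/G	G/G
recessive	CSNK1A1L	rs9576175	G	0			T/T	T/T	T/T
recessive	HLA-C	rs79636386	A	1			C/C	C/C	C/C
recessive	HLA-DQB1	rs1049130	A	1			G/G	G/G	G/G
recessive	KRTAP19-4	rs2298437	T	0			C/C	C/C	C/C
recessive	LCE5A	rs2105117	G	0			A/A	A/A	A/A
recessive	MMRN2	rs3750823	C	0			T/T	T/T	T/T
recessive	NFATC4	rs7149586	T	1			C/C	C/C	C/C
recessive	PM20D1	rs1361754	A	0			G/G	G/G	G/G
recessive	RTP1	rs6764714	C	1			G/G	G/G	G/G
recessive	SIM2	rs2073601	C	1			A/A	A/A	A/A
recessive	TINAG	rs1058768	T	0			C/C	C/C	C/C
recessive	TMED5	rs1060622	G	0			A/A	A/A	A/A
recessive	TMEM173	rs1131769	T	1			C/C	C/C	C/C
recessive	TPTE	novel	G	0	novel 21:g.10951387T>G missense		T/T	T/T	T/T
recessive	ZC3H13	rs9534264	T	1			A/A	A/A	A/A
dominant	ACBD3	rs2306120	T	0			T/G	T/G	T/G
dominant	ALPK2	rs9944810	C	0			C/A	C/A	C/A
dominant	ANKK1	rs1800497	G	0			G/A	G/A	G/A
dominant	ART4	rs11276	C	0			C/T	C/T	C/T
dominant	BBS12	rs309370	G	0			G/A	G/A	G/A
dominant	BBS12	rs13135778	G	0			G/A	G/A	G/A
dominant	C12orf60	rs139293175	CTA	0			CTA/C	CTA/C	CTA/C
dominant	C12orf60	rs7307438	T	0			T/A	T/A	T/A
dominant	CCDC144NL	rs79930314	G	0			G/T	G/T	G/T
dominant	CCDC144NL	rs79843086	G	0			G/T	G/T	G/T
dominant	CCHCR1	rs130068	G	0			G/A	G/A	G/A
dominant	CD200	rs2272022	C	1			C/A	C/A	C/A
dominant	CWF19L2	rs659040	G	0			G/A	G/A	G/A
dominant	CYP21A2	rs397515530	G	0			A/A	A/A	G/A
dominant	DHRS4	rs17099455	G	0			G/A	G/A	G/A
dominant	DYNC2LI1	rs9309107	T	0			T/A	T/A	T/A
dominant	EDN1	rs5370	G	0			G/T	T/T	G/T
dominant	EFS	rs2231798	T	0			T/C	T/C	T/C
dominant	EPCAM	rs1126497	T	0			T/C	T/C	T/C
dominant	FHAD1	rs4661330	A	0			A/G	A/G	A/G
dominant	HINFP	rs100803	C	0			C/T	C/T	C/T
dominant	HLA-C	rs79636386	A	1		A/C	C/C	C/C	C/C
dominant	HLA-DQB1	rs1130398	C	1			C/T	C/T	C/T
dominant	HLA-DQB1	rs1063323	C	1			C/T	C/T	C/T
dominant	HLA-DRB1	rs71547382	C	1			C/T	C/T	C/T
dominant	KIF20B	rs1886997	A	0			A/G	A/G	A/G
dominant	KIF20B	rs144593231	C	0			C/CTAAAAG	C/CTAAAAG	C/CTAAAAG
dominant	KLHL33	rs1953225	T	0			T/C	T/C	T/C
dominant	KRT40	rs9908304	G	0			G/A	G/A	G/A
dominant	LRRC6	rs2293979	G	0			A/A	G/A	G/A
dominant	MCCD1	rs2259435	G	1			G/A	G/A	G/A
dominant	MICB	rs1065075	A	1	EVS		A/G	A/G	A/G
dominant	MICB	rs1051788	G	1	EVS		G/A	G/A	G/A
dominant	MMP27	rs1276286	T	0			T/A	T/A	A/A
dominant	NOS2	rs2297518	G	1			G/A	G/A	G/A
dominant	NPAS2	rs9223	C	0		C/T	C/T	C/T	C/T
dominant	NPY4R	rs79871698	G	1			G/A	G/A	G/A
dominant	NRG3	rs1884282	C	1			C/G	C/G	C/G
dominant	NSUN4	rs3737744	A	0			A/G	A/G	A/G
dominant	NUMBL	rs749669311	TTTGCTGTTGCTGCTGCTGC	1			TTTGCTGTTGCTGCTGCTGC/T	TTTGCTGTTGCTGCTGCTGC/T	TTTGCTGTTGCTGCTGCTGC/T
dominant	OR10G2	rs41314525	C	0			C/A	C/A	C/A
dominant	OR13C2	rs10156474	T	0			T/C	T/C	T/C
dominant	OR13C2	rs10991326	A	0			A/T	A/T	A/T
dominant	OR13C5	rs4117966	C	0			C/T	C/T	C/T
dominant	OR13C5	rs1523678	T	0			T/C	T/C	T/C
dominant	OR13C5	rs1851725	A	0			A/G	A/G	A/G
dominant	OR13C5	rs6479260	G	0			G/C	G/C	G/C
dominant	OR13C5	rs11314210	GT	0			GT/G	GT/G	GT/G
dominant	OR13C9	rs993658	T	0			T/A	T/A	T/A
dominant	OR2T2	rs67700848	C	0			C/T	C/T	C/T
dominant	OR4E2	rs61732411	C	0		C/T	C/T	C/T	C/T
dominant	PRDM1	rs811925	C	1			C/G	C/G	C/G
dominant	PSMD9	rs14259	A	1			A/G	A/G	A/G
dominant	RNLS	rs2296545	C	0			C/G	C/G	C/G
dominant	SPATA16	rs1515441	C	0			C/T	C/T	C/T
dominant	SPATA16	rs16846616	C	0			C/T	C/T	C/T
dominant	SVEP1	rs3739451	A	0			A/T	A/T	A/T
dominant	TMEM132C	rs12424159	G	0			G/A	G/A	G/A
dominant	TMEM71	rs1895807	A	0			A/G	A/G	A/G
dominant	WDR66	rs17852561	C	0			C/T	C/T	C/T
dominant	WWC2	rs11734376	G	0			G/T	G/T	G/T
dominant	ZNF626	rs73002662	T	0			T/G	T/G	T/G
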