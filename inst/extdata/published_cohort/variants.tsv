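chrom	pos	ref	alt	gene	cdna_change	protein_change	consequence	dbsnp_maf	kg_maf	exac_ac	exac_an	exac_hom	nbk_maf	pp2	mutation_taster	provean	sift	hgmd_listed	conservation_depth
7	107350577	A	G	SLC26A4	c.2168A>G	p.His723Arg	missense	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
7	107314575	A	G	SLC26A4	c.439A>G	p.Met147Val	missense	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
7	107323898	A	G	SLC26A4	c.919-2A>G	NA	splice_site	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
7	107348505	A	AT	SLC26A4	c.2027_2028insT	p.Arg677Alafs*11	frameshift_insertion	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
7	107329573	C	T	SLC26A4	c.1229C>T	p.Thr410Met	missense	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
7	107301202	C	A	SLC26A4	c.81C>A	p.Tyr27*	nonsense	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	NA
7	107323917	G	GG	SLC26A4	c.916_917insG	p.Val306Glyfs*24	frameshift_insertion	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
13	20763010	C	CAGAAGACTGTCTTCACAGTGTTCATGATTGCAGTGTCTGGAATTTG	GJB2	c.605_606ins46	p.Cys202*	inframe_indel	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
13	20763686	G	A	GJB2	c.9G>A	p.Trp3*	nonsense	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
13	20763460	AC	A	GJB2	c.235delC	p.Leu79Cysfs*3	frameshift_deletion	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
13	20763268	C	T	GJB2	c.427C>T	p.Arg143Trp	missense	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
13	20763395	CAT	C	GJB2	c.299_300delAT	p.His100Argfs*14	frameshift_deletion	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	TRUE	NA
17	18070000	C	A	MYO15A	c.7990C>A	p.Pro2664Thr	missense	0.0002	NA	12	118432	0	0.00377834	0.026	polymorphism	-2.55	0.028	NA	3
17	18075000	T	C	MYO15A	c.9221T>C	p.Met3074Thr	missense	0.0002	NA	1	120686	0	NA	0.006	disease_causing	-2.08	0.184	NA	2
17	18045000	G	T	MYO15A	c.4322G>T	p.Gly1441Val	missense	NA	NA	1	116996	0	NA	1.000	disease_causing	-8.66	0.000	NA	4
17	18025000	G	A	MYO15A	c.1651G>A	p.Ala551Thr	missense	NA	NA	NA	NA	NA	NA	0.004	polymorphism	-0.82	0.012	NA	2
10	73550000	G	A	CDH23	c.7145G>A	p.Arg2382Gln	missense	0.00002	NA	3	120700	0	NA	0.977	NA	-0.77	0.001	NA	4
10	73560000	C	T	CDH23	c.7361C>T	p.Thr2454Met	missense	0.0001	NA	12	120752	0	NA	0.998	NA	-3.18	0.001	NA	4
11	76900000	C	T	MYO7A	c.1373C>T	p.Ala458Val	missense	NA	NA	2	121000	0	NA	0.88	disease_causing	-3.6	0.02	NA	3
7	24748000	G	A	DFNA5	c.1406G>A	p.Arg469His	missense	NA	NA	1	121000	0	NA	0.71	disease_causing	-2.9	0.03	NA	3
10	55580000	C	T	PCDH15	c.400C>T	p.Arg134Cys	missense	NA	NA	4	121000	0	NA	0.92	disease_causing	-4.1	0.01	NA	3
10	26210000	G	A	MYO3A	c.1777G>A	p.Val593Met	missense	NA	NA	6	121000	0	NA	0.55	polymorphism	-2.7	0.04	NA	2
21	45920000	C	T	TSPEAR	c.1583C>T	p.Thr528Met	missense	NA	NA	9	121000	0	NA	0.63	polymorphism	-2.1	0.09	NA	2
19	3590000	C	T	GIPC3	c.785C>T	p.Ala262Val	missense	NA	NA	5	121000	0	NA	0.50	polymorphism	-1.9	0.10	NA	2
18	44100000	G	A	LOXHD1	c.4480G>A	p.Glu1494Lys	missense	NA	NA	3	121000	0	NA	0.60	polymorphism	-2.2	0.07	NA	2
1	236720000	G	A	HEATR1	c.301G>A	p.Gly101Ser	missense	NA	NA	2	121000	0	NA	0.81	disease_causing	-3.3	0.02	NA	3
1	236740000	C	T	HEATR1	c.2210C>T	p.Ser737Leu	missense	NA	NA	1	121000	0	NA	0.77	disease_causing	-2.8	0.03	NA	3
X	129500000	G	A	SLC25A14	c.650G>A	p.Arg217His	missense	NA	NA	3	121000	0	NA	0.69	disease_causing	-3.0	0.02	NA	3
X	48200000	C	T	SSX3	c.220C>T	p.Arg74Trp	missense	NA	NA	1	121000	0	NA	0.74	disease_causing	-4.2	0.01	NA	2
15	84380000	G	A	ADAMTSL3	c.2821G>A	p.Asp941Asn	missense	NA	NA	2	121000	0	NA	0.66	disease_causing	-2.9	0.03	NA	3
11	2340000	C	T	CEND1	c.343C>T	p.Arg115Cys	missense	NA	NA	1	121000	0	NA	0.83	disease_causing	-3.8	0.01	NA	3
21	36590000	G	A	DOPEY2	c.5042G>A	p.Arg1681His	missense	NA	NA	2	121000	0	NA	0.58	polymorphism	-2.6	0.04	NA	2
9	137050000	C	T	SWI5	c.190C>T	p.Arg64Trp	missense	NA	NA	1	121000	0	NA	0.72	disease_causing	-3.1	0.02	NA	3
3	12840000	G	A	CAND2	c.2468G>A	p.Arg823Gln	missense	NA	NA	3	121000	0	NA	0.61	disease_causing	-2.7	0.03	NA	2
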