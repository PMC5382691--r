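symbol	inheritance	chrom	n_exons
SLC26A4	AR	7	21
GJB2	AR	13	2
MYO15A	AR	17	66
CDH23	AR	10	70
MYO7A	AR,AD	11	49
OTOF	AR	2	48
TMC1	AR,AD	9	24
TMPRSS3	AR	21	13
PCDH15	AR	10	35
MYO3A	AR	10	35
TSPEAR	AR	21	12
GIPC3	AR	19	6
LOXHD1	AR	18	36
GRXCR2	AR	5	4
FAM65B	AR	6	16
KARS	AR	16	15
TRIOBP	AR	22	24
SLC26A5	AR	7	14
ESRRB	AR	14	10
GJB6	AR,AD	13	3
USH1C	AR	11	27
WHRN	AR	9	13
MARVELD2	AR	5	7
COL11A2	AR,AD	6	62
PJVK	AR	2	7
LRTOMT	AR	11	10
HGF	AR	7	18
BSND	AR	1	4
CABP2	AR	11	7
CIB2	AR	15	6
CLDN14	AR	21	3
EPS8	AR	12	20
GPSM2	AR	1	15
LHFPL5	AR	6	4
MSRB3	AR	12	8
MYO6	AR,AD	6	35
OTOA	AR	16	28
OTOG	AR	11	45
OTOGL	AR	12	48
PTPRQ	AR	12	40
RDX	AR	11	14
SERPINB6	AR	6	8
STRC	AR	15	26
SYNE4	AR	19	7
TBC1D24	AR,AD	16	8
TPRN	AR	9	4
DCDC2	AR	6	10
KCNQ4	AD	1	14
COCH	AD	14	12
DFNA5	AD	7	10
WFS1	AD,AR	4	8
GRHL2	AD	8	16
MYH14	AD	19	37
MYH9	AD	22	35
ACTG1	AD	17	6
CEACAM16	AD	19	7
DIAPH1	AD	5	23
EYA4	AD	6	20
GJB3	AD	1	2
P2RX2	AD	12	11
POU4F3	AD	5	2
SLC17A8	AD	12	12
TJP2	AD	9	23
TECTA	AD,AR	11	23
SIX1	AD	14	2
OSBPL2	AD	20	15
TNC	AD	9	25
GRXCR1	AR	4	4
POU3F4	XL	X	1
PRPS1	XL	X	7
SMPX	XL	X	5
COL4A6	XL	X	33
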