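YUEVA38	YUEVA38	0	0	1	2
YUEVA59	YUEVA59	0	0	1	2
YUEVA60	YUEVA60	0	0	1	2
YUEVA61	YUEVA61	0	0	2	2
YUEVA65	YUEVA65	0	0	1	2
YUEVA67	YUEVA67	0	0	1	2
YUEVA69	YUEVA69	0	0	1	2
YUEVA72	YUEVA72	0	0	1	2
YUEVA73	YUEVA73	0	0	1	2
YUEVA74	YUEVA74	0	0	2	2
YUEVA77	YUEVA77	0	0	2	2
YUEVA111	YUEVA111	0	0	1	2
YUHL6	YUHL6-21	0	0	2	2
YUHL11	YUHL11-21	0	0	1	2
YUHL19	YUHL19-21	0	0	2	2
YUHL8	YUHL8-21	0	0	2	2
YUHL13	YUHL13-21	YUHL13-11	YUHL13-12	1	2
YUHL13	YUHL13-11	0	0	1	1
YUHL13	YUHL13-12	0	0	2	1
YUHL24	YUHL24-21	YUHL24-11	0	2	2
YUHL24	YUHL24-11	0	0	1	1
YUHL10	YUHL10-21	0	0	1	2
YUHL14	YUHL14-21	0	0	2	2
YUHL20	YUHL20-21	0	0	1	2
YUHL26	YUHL26-21	YUHL26-11	YUHL26-12	2	2
YUHL26	YUHL26-11	0	0	1	1
YUHL26	YUHL26-12	0	0	2	1
YUHL30	YUHL30-21	0	0	2	2
YUHL33	YUHL33-21	0	0	2	2
YUHL36	YUHL36-21	0	0	1	2
YUHL40	YUHL40-21	0	0	2	2
YUHL44	YUHL44-21	YUHL44-11	YUHL44-12	1	2
YUHL44	YUHL44-11	0	0	1	1
YUHL44	YUHL44-12	0	0	2	1
YUHL45	YUHL45-21	0	0	2	2
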