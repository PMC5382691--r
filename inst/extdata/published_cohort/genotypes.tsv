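subject_id	variant_id	zygosity
YUEVA38	7:107350577:A:G	het
YUEVA38	7:107314575:A:G	het
YUEVA59	7:107350577:A:G	het
YUEVA59	7:107323898:A:G	het
YUEVA60	7:107348505:A:AT	het
YUEVA60	7:107350577:A:G	het
YUEVA61	7:107350577:A:G	het
YUEVA61	7:107323898:A:G	het
YUEVA65	7:107329573:C:T	het
YUEVA65	7:107301202:C:A	het
YUEVA67	7:107350577:A:G	het
YUEVA67	7:107323898:A:G	het
YUEVA69	7:107350577:A:G	het
YUEVA69	7:107314575:A:G	het
YUEVA72	7:107350577:A:G	het
YUEVA72	7:107323898:A:G	het
YUEVA73	7:107350577:A:G	het
YUEVA73	7:107314575:A:G	het
YUEVA74	7:107350577:A:G	hom_alt
YUEVA77	7:107350577:A:G	hom_alt
YUEVA111	7:107323917:G:GG	het
YUEVA111	7:107323898:A:G	het
YUHL6-21	13:20763010:C:CAGAAGACTGTCTTCACAGTGTTCATGATTGCAGTGTCTGGAATTTG	het
YUHL6-21	13:20763686:G:A	het
YUHL11-21	13:20763460:AC:A	het
YUHL11-21	13:20763268:C:T	het
YUHL19-21	13:20763395:CAT:C	het
YUHL19-21	13:20763268:C:T	het
YUHL8-21	17:18070000:C:A	het
YUHL8-21	17:18075000:T:C	het
YUHL13-21	17:18045000:G:T	het
YUHL13-21	17:18025000:G:A	het
YUHL13-11	17:18045000:G:T	het
YUHL13-12	17:18025000:G:A	het
YUHL13-21	19:3590000:C:T	het
YUHL13-21	18:44100000:G:A	het
YUHL24-21	10:73550000:G:A	het
YUHL24-21	10:73560000:C:T	het
YUHL24-11	10:73550000:G:A	het
YUHL26-21	11:76900000:C:T	het
YUHL26-12	11:76900000:C:T	het
YUHL26-21	10:26210000:G:A	het
YUHL44-21	7:24748000:G:A	het
YUHL44-12	7:24748000:G:A	het
YUHL44-21	1:236720000:G:A	het
YUHL44-21	1:236740000:C:T	het
YUHL44-11	1:236720000:G:A	het
YUHL44-12	1:236740000:C:T	het
YUHL44-21	X:129500000:G:A	hemizygous
YUHL44-12	X:129500000:G:A	het
YUHL44-21	X:48200000:C:T	hemizygous
YUHL44-12	X:48200000:C:T	het
YUHL44-21	15:84380000:G:A	het
YUHL44-21	11:2340000:C:T	het
YUHL44-21	21:36590000:G:A	het
YUHL44-21	9:137050000:C:T	het
YUHL44-21	3:12840000:G:A	het
YUHL14-21	10:55580000:C:T	het
YUHL36-21	21:45920000:C:T	het
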