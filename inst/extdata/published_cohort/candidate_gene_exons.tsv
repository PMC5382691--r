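gene	exon_index	chrom	start	end
MUC22	1	6	30978000	30978200
MUC22	2	6	30990000	30990150
MUC22	3	6	30994500	30997000
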