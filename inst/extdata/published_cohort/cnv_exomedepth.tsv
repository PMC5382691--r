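subject_id	caller	chrom	start	end	type	copy_number
YUHL10-21	ExomeDepth	6	30995000	30996700	deletion	0
YUHL10-21	ExomeDepth	2	10010000	10035000	deletion	1
YUHL20-21	ExomeDepth	8	8000000	8050000	duplication	3
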