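subject_id	caller	chrom	start	end	type	copy_number
YUHL10-21	EXCAVATOR	6	30995157	30996641	deletion	0
YUHL10-21	EXCAVATOR	2	10000000	10040000	deletion	1
YUHL14-21	EXCAVATOR	5	50000000	50030000	duplication	3
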