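rank	species
0	not_conserved
1	primates
2	M_musculus
3	G_gallus
4	D_rerio
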