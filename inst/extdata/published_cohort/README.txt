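Fixture cohort: 28 probands with sporadic severe-to-profound NSHL.

This is a SYNTHETIC RECONSTRUCTION of a published cohort's genotype tables:
the diagnostic alleles (genes, cDNA/protein changes, zygosities, segregation,
frequency and in-silico annotations where printed) follow the published
mutation tables, but all genomic coordinates are invented placeholders on the
correct chromosomes, and the alleles that were only described in
supplementary material (the non-segregating dominant variants, the candidate
variants of one WES-unsolved subject, the CNV call lists, and the candidate
gene's exon model) are plausible stand-ins consistent with the main text.
Subject ids YUHL30/33/40/45 are invented labels for unsolved subjects whose
ids were not printed.
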