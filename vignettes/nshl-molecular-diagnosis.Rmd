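---
title: "Molecular diagnosis of sporadic non-syndromic hearing loss: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular diagnosis of sporadic non-syndromic hearing loss: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nshldx)
```

## The diagnostic problem

Severe-to-profound congenital hearing loss in a simplex family — one
affected child, hearing parents, no family history — is usually genetic and
usually autosomal recessive: both parents are silent heterozygous carriers,
or the allele arose de novo. Molecular diagnosis therefore cannot lean on
segregation across many affected relatives; it must prioritize the
~10^5 variants of a single exome down to one or two alleles whose genotype
*mechanism* (bi-allelic, hemizygous, de novo) can explain a recessive-like
sporadic presentation. `nshldx` encodes that reasoning as a reusable,
testable pipeline: a staged clinical triage, a six-step filter cascade with
a per-step audit trail, pedigree-logical genotype mechanics, a capture
coverage audit, CNV consensus, and cohort-level yield reporting.

## Staged triage

Subjects with an enlarged vestibular aqueduct (EVA) on temporal-bone
imaging are evaluated by full *SLC26A4* Sanger sequencing first, subjects
without EVA by *GJB2*; only subjects undiagnosed after this pre-screen are
routed to whole-exome analysis. The triage order matters for reporting:
cohort yield is additionally stratified as "excluding the *SLC26A4* Sanger
route" and "within WES-routed subjects", because the imaging-directed route
concentrates easily diagnosed subjects and inflates the headline yield.
The Sanger stages evaluate the gene's genotypes directly (Sanger sees every
exon); the frequency/consequence cascade applies to the exome stage.

## The filter cascade

Six steps run in a fixed order, each recording its surviving count and the
first step that removed every excluded variant, so each run produces a
complete, monotone waterfall:

1. **Population frequency** — remove variants with dbSNP or 1000 Genomes
   MAF strictly above 1%. Only these two databases act here; the other
   frequency sources participate at step 6. A variant absent from both
   databases is never removed at this step.
2. **Internal controls** — remove variants seen homozygous or
   hemizygous in a panel of unaffected controls (32 by default).
   Heterozygous control carriers do *not* exclude: unaffected carriers are
   exactly what recessive inheritance predicts.
3. **Consequence** — remove synonymous and non-splice intronic variants.
   The consequence vocabulary is closed (nine labels); an unknown label is
   an error, not a silent pass. "Splice site" is its own label, assigned
   upstream by the annotator for the canonical ±2 bp dinucleotide window.
4. **Panel restriction** — partition by membership in the 72-gene NSHL
   panel. Both partitions survive: known-gene diagnosis is attempted first,
   and genome-wide candidate discovery runs only if the panel yields no
   diagnostic genotype (`force_candidate` overrides, for exploration).
5. **Inheritance mechanism** — keep homozygous-alternate genotypes, genes
   carrying two or more heterozygous variants, hemizygous X genotypes in
   males, and de novo heterozygous variants (trio only). Any other
   heterozygous singleton is dropped — with bookkeeping: dominant-gene
   singletons get a segregation verdict, recessive-gene singletons are kept
   as "one allele found" observations for the coverage worklist.
6. **Mode-specific rarity and ranking** — re-filter on the worst-case
   frequency across all databases (ExAC as allele count / allele number):
   strictly below 0.005 for recessive genes, 0.0005 for dominant-only
   genes; rank by damaging in-silico votes (PolyPhen-2 ≥ 0.5,
   MutationTaster disease-causing, PROVEAN ≤ −2.5, SIFT ≤ 0.05),
   then conservation depth, then rarity, with the variant id as a stable
   tie-break.

Boundary conventions follow the inequality directions of their sources
literally: step 1 removes strictly *above* 1% (so exactly 0.01 is kept),
step 6 keeps strictly *below* its cuts. X-linked genes use the recessive
cut: hemizygous exposure behaves like recessive inheritance, and no
dominant-specific threshold is established for them. Absent annotations
are neutral throughout — a missing frequency is treated as 0 for
thresholding (a variant unseen by every database is rare, not suspicious),
and a missing score casts no damaging vote.

## Pedigree-logical genotype mechanics

Compound heterozygotes are causative only *in trans* (one allele per
parental haplotype). `resolve_phase()` decides by exhaustively enumerating
phased parental diplotypes and transmitted haplotypes consistent with the
proband being heterozygous at both loci: if every consistent transmission
is trans the pair is `confirmed_trans`; if every one is cis it is
`cis_rejected` (never diagnostic); a mixture, or untyped parents, leaves
`presumed_unconfirmed` — still reportable as causative, mirroring clinical
practice when parental DNA is unavailable, but flagged as unconfirmed. A
deliberate conservative choice: when one parent carries both alleles and
the other carries one, transmission is ambiguous and the pair stays
presumed rather than confirmed. Alleles carried by neither typed parent
are marked de novo in the parental-origin map.

De novo status requires a genotyped trio — a singleton heterozygote can
never be promoted. Dominant-gene variants carried by a typed unaffected
parent are `non_segregating` and excluded from diagnosis; with untyped
parents a dominant singleton is `indeterminate`, also never counted. A
segregating de novo variant in a dominant-mode panel gene *is* accepted as
a diagnosis, with an explicit note — the mechanism is sound even though no
such case occurs in the fixture cohort, so the behaviour is an extension
beyond the observed data.

Cross-gene heterozygous pairs (possible digenic inheritance) are
deliberately not called: the engine records recessive-gene singletons as
observations only.

## Coverage audit and CNV consensus

Exome capture leaves some panel exons dark. The audit takes a per-exon
depth table and reports exons with depth strictly below 1, split into
*not targeted by the capture design* and *targeted but uncovered*. Depth
is the per-exon mean; "read depth below one" does not distinguish per-base
from per-exon summaries, so the mean was chosen and a per-base minimum
column can be audited via the `use` argument. The Sanger worklist encodes
two follow-up rules: every uncovered exon of a dominant-mode gene (one
missed heterozygous allele could be the whole diagnosis), and uncovered
exons of recessive genes only for subjects already carrying one
heterozygous allele there (the hidden second hit).

Two read-depth CNV call sets are merged by requiring matching call type
and reciprocal overlap of at least 0.5; the consensus interval is the
intersection and the consensus copy number the minimum of the pair. Both
rules are package decisions (no published merge procedure exists for this
pairing) and both are arguments. Consensus deletions with copy number 0
that intersect a coding exon are flagged as recessive-pattern candidate
findings — truncating both copies of a gene — but never counted as
diagnoses.

## The synthetic cohort generator

The generator exists so the pipeline's claims are testable end to end. It
emulates:

* a shared pool of exome sites (default 2,000; 170,215 reproduces full
  exome scale) with MAFs from a two-component mixture — common sites
  (90% of the pool) uniform on [0.02, 0.5], rare sites log-uniform on
  [10⁻⁶, 5×10⁻³];
* database incompleteness: common sites are known to dbSNP with
  probability 0.99, rare sites 0.3; unknown sites carry no population
  frequency and therefore survive the frequency step, which is what makes
  the waterfall's middle tier ("hundreds surviving step 1") emerge at
  exome scale rather than being hard-coded;
* Hardy–Weinberg genotypes for parents and internal controls at each
  site's MAF, with single-allele draws for males on X outside the
  pseudo-autosomal regions, and Mendelian transmission to trio children;
* planted genotypes of each mechanism class at fresh exonic loci of panel
  genes with the required mode — plus two decoy classes (a lone
  heterozygous recessive allele; a dominant allele shared with the
  unaffected mother) that must never be called solved;
* per-exon capture depths with a configurable number of untargeted and
  targeted-but-uncovered gaps (covered exons draw around a mean of 65.8),
  and fabricated caller pairs for the CNV consensus.

Calibration choices stated once: planted causal alleles are rare by
construction (below the recessive cut; dominant plants below the dominant
cut — a "causal" allele that fails its own mode's rarity threshold would
contradict the thresholds' definition), and internal controls may carry a
planted allele heterozygously but never homozygously or hemizygously,
because controls are unaffected and the phenotype is fully penetrant
congenital deafness. Background sites carry synthetic non-panel gene
symbols, so panel genotypes arise only from plants; consequently planted
recovery is exact by construction, and the generator does not model benign
common variation *inside* panel genes (a real exome would show panel-gene
singletons that step 5 must discard — the fixture cohort covers that
behaviour instead).

What passing synthetic tests does **not** show about real data: no linkage
disequilibrium between sites, no sequencing or genotyping error, no
population stratification between cohort and frequency databases, no
mosaicism, and annotation fields are internally consistent by
construction. The generator validates the pipeline's logic, not the
error-tolerance of real exomes.

## The fixture cohort

`load_published_cohort()` ships a 28-subject cohort transcribed from a
published mutation table: 12 probands with bi-allelic *SLC26A4*
genotypes, 3 with *GJB2*, 2 with compound-heterozygous *MYO15A*, 1 with
*CDH23*, and 10 WES-unsolved subjects including the two non-segregating
dominant decoys and the *MUC22* bi-allelic deletion carrier. Genomic
coordinates, supplementary-only alleles and four unsolved subject ids are
synthetic stand-ins, documented in the fixture's README. The expected
outputs — 18/28 solved (64.3%), 6/16 (37.5%) after removing the
*SLC26A4*-routed subjects, 3/13 (23.1%) within WES — are recomputed by the
test suite and `scripts/acceptance.R`, never asserted as constants in
package code.

Percentages round half away from zero to one decimal, the convention that
makes 18/28 print as 64.3 and 3/13 as 23.1.

## Numerical and scale choices

Deterministic behaviour everywhere: one seed drives a whole generated
cohort; ranking ties break lexicographically; classification of identical
inputs is identical. The test suite runs the recovery study at 20 cohorts
of 28 probands over 2,000-site pools, and the exome-scale waterfall on one
170,215-site trio — sizes chosen so the full suite completes in about a
minute while still exercising every code path at realistic proportions;
filter behaviour is count-invariant, so structure rather than raw totals
is what the assertions check.

## Known limitations

* Phase is pedigree-logical only; no read-backed phasing.
* The panel's exon coordinates are synthesized (no transcript model is
  bundled); interval logic is internally consistent but not liftable to a
  reference genome.
* Digenic hypotheses are recorded, never resolved.
* The CNV stage consumes caller outputs; it does not segment read depth.
* Variant calling, alignment and annotation are upstream of this package:
  inputs are expected as decomposed, annotated variant tables (VCF with
  the documented INFO keys, or a sidecar TSV).
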