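# Shared in-code fixtures: a miniature gene panel, variant/cohort builders,
# and an independent brute-force phase oracle.

# a 4-gene panel exercising every inheritance mode, built through the
# TSV+BED reader so the external interface is used everywhere
test_panel <- function() {
  genes <- data.frame(
    symbol = c("AGENE", "BGENE", "DGENE", "XGENE"),
    inheritance = c("AR", "AR,AD", "AD", "XL")
  )
  bed <- data.frame(
    chrom = c("1", "1", "3", "2", "X"),
    start = c(999, 4999, 1999, 2999, 49999999),   # BED 0-based
    end = c(1150, 5150, 2150, 3150, 50000150),
    name = c("AGENE:1", "AGENE:2", "BGENE:1", "DGENE:1", "XGENE:1"),
    score = 1L
  )
  gt <- tempfile(fileext = ".tsv"); bt <- tempfile(fileext = ".bed")
  write.table(genes, gt, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bed, bt, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  load_gene_panel(gt, bt)
}

# quick variant rows: rare damaging missense by default
mk_var <- function(chrom, pos, gene, ref = "A", alt = "G",
                   consequence = "missense", dbsnp_maf = NA_real_,
                   kg_maf = NA_real_, exac_ac = NA_real_, exac_an = NA_real_,
                   nbk_maf = NA_real_, pp2 = 0.9,
                   mutation_taster = "disease_causing", provean = -4,
                   sift = 0.01, conservation_depth = 3L,
                   hgmd_listed = FALSE) {
  tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, consequence = consequence, dbsnp_maf = dbsnp_maf,
    kg_maf = kg_maf, exac_ac = exac_ac, exac_an = exac_an, nbk_maf = nbk_maf,
    pp2 = pp2, mutation_taster = mutation_taster, provean = provean,
    sift = sift, conservation_depth = conservation_depth,
    hgmd_listed = hgmd_listed
  )
}

mk_ped <- function(proband = "P1", father = NA_character_,
                   mother = NA_character_, sex = "female") {
  tibble::tibble(family_id = proband, proband_id = proband,
                 father_id = father, mother_id = mother, proband_sex = sex,
                 trio = !is.na(father) & !is.na(mother))
}

mk_geno <- function(subject, vid, zyg) {
  tibble::tibble(subject_id = subject, variant_id = vid, zygosity = zyg)
}

mk_cohort <- function(variants, genotypes, pedigrees, panel = test_panel(),
                      controls = NULL, subjects = NULL, cnv_flags = NULL) {
  if (is.null(subjects)) {
    subjects <- tibble::tibble(subject_id = pedigrees$proband_id,
                               family_id = pedigrees$family_id,
                               sex = pedigrees$proband_sex, eva = FALSE)
  }
  structure(list(subjects = subjects, pedigrees = pedigrees,
                 variants = as_variant_table(variants), genotypes = genotypes,
                 controls = controls, panel = panel, cnv_flags = cnv_flags),
            class = "nshl_cohort")
}

# a two-variant trio with the proband het at both loci and the given
# parental zygosities
two_locus_setup <- function(fzA, fzB, mzA, mzB) {
  ped <- mk_ped("P1", father = "F1", mother = "M1")
  g <- dplyr::bind_rows(
    mk_geno("P1", "1:100:A:G", "het"),
    mk_geno("P1", "1:200:C:T", "het"),
    if (fzA != "hom_ref") mk_geno("F1", "1:100:A:G", fzA),
    if (fzB != "hom_ref") mk_geno("F1", "1:200:C:T", fzB),
    if (mzA != "hom_ref") mk_geno("M1", "1:100:A:G", mzA),
    if (mzB != "hom_ref") mk_geno("M1", "1:200:C:T", mzB))
  list(ped = ped, g = g)
}

# ---- independent phase oracle -------------------------------------------
# Brute-force enumeration of haplotype transmissions for a two-locus pair:
# parents are typed with zygosities in {hom_ref, het, hom_alt} per locus;
# the child is het at both. Returns "trans" / "cis" / "mixed" / "none".
oracle_phase <- function(fzA, fzB, mzA, mzB) {
  alleles <- function(z) switch(z, hom_ref = c(0, 0), het = c(0, 1),
                                hom_alt = c(1, 1))
  diplos <- function(zA, zB) {
    aA <- alleles(zA); aB <- alleles(zB)
    out <- list()
    for (pa in list(aA, rev(aA))) for (pb in list(aB, rev(aB))) {
      out[[length(out) + 1L]] <- rbind(c(pa[1], pb[1]), c(pa[2], pb[2]))
    }
    unique(out)
  }
  res <- character(0)
  for (fd in diplos(fzA, fzB)) for (md in diplos(mzA, mzB)) {
    for (fi in 1:2) for (mi in 1:2) {
      fh <- fd[fi, ]; mh <- md[mi, ]
      if (fh[1] + mh[1] == 1 && fh[2] + mh[2] == 1) {
        res <- c(res, if (all(fh == 1) || all(mh == 1)) "cis" else "trans")
      }
    }
  }
  if (length(res) == 0) return("none")
  if (all(res == "trans")) return("trans")
  if (all(res == "cis")) return("cis")
  "mixed"
}
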