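#' Pedigree-aware inheritance mechanics
#'
#' These functions operate on a genotype table in "carrier" convention:
#' one row per (subject, variant) with a zygosity in [ZYGOSITIES]. A subject
#' listed in the pedigree but with no row at a variant is taken as hom_ref
#' (typed, reference); a parent not listed in the pedigree is untyped.
#' @name inheritance
NULL

# zygosity of one subject at one variant under the carrier convention
zygosity_of <- function(genotypes, subject_id, vid) {
  if (is.na(subject_id)) return(NA_character_)  # untyped member
  hit <- genotypes$zygosity[genotypes$subject_id == subject_id &
                              genotypes$variant_id == vid]
  if (length(hit) == 0) return("hom_ref")
  if (hit[1] == "missing") return(NA_character_)
  hit[1]
}

carries <- function(zyg) !is.na(zyg) & zyg %in% c("het", "hom_alt", "hemizygous")

# allele multisets per locus for one parent; NULL marks an untyped parent
parent_alleles <- function(zyg) {
  switch(zyg,
    hom_ref = c(0L, 0L), het = c(0L, 1L), hom_alt = c(1L, 1L),
    hemizygous = 1L,
    NULL
  )
}

# all phased diplotypes of one parent over two loci: a list of haplotype
# matrices (one row per haplotype, columns = locus A, locus B)
parent_diplotypes <- function(zygA, zygB) {
  aA <- parent_alleles(zygA)
  aB <- parent_alleles(zygB)
  if (is.null(aA) || is.null(aB)) return(NULL)
  if (length(aA) == 1 || length(aB) == 1) {
    # hemizygous at either locus: a single haplotype carries both loci
    return(list(matrix(c(aA[1], aB[1]), nrow = 1)))
  }
  phasings <- list(
    matrix(c(aA[1], aA[2], aB[1], aB[2]), nrow = 2),
    matrix(c(aA[1], aA[2], aB[2], aB[1]), nrow = 2)
  )
  unique(phasings)
}

#' Resolve the phase of two heterozygous variants from parental genotypes
#'
#' Enumerates every phased parental diplotype and transmitted-haplotype
#' combination consistent with the proband being heterozygous at both loci.
#' If every consistent transmission places the two alternate alleles on
#' haplotypes from different parents the pair is `confirmed_trans`; if every
#' one places them on the same transmitted haplotype it is `cis_rejected`;
#' a mix (or untyped parents) is `presumed_unconfirmed`. A variant carried
#' by neither typed parent is flagged de novo in the parental-origin map and
#' the pair stays `presumed_unconfirmed`.
#'
#' @param varA,varB variant ids of the two heterozygous alleles
#' @param genotypes genotype table (carrier convention)
#' @param pedigree one pedigree row (see [read_pedigrees()])
#' @return list with `phase_status` (one of confirmed_trans, cis_rejected,
#'   presumed_unconfirmed) and `parental_origin`, a named character vector
#'   over the two variant ids with values father/mother/de_novo/unknown
#' @export
resolve_phase <- function(varA, varB, genotypes, pedigree) {
  pid <- pedigree$proband_id
  pzA <- zygosity_of(genotypes, pid, varA)
  pzB <- zygosity_of(genotypes, pid, varB)
  if (!identical(pzA, "het") || !identical(pzB, "het")) {
    abort("resolve_phase requires the proband to be heterozygous at both loci")
  }
  fzA <- zygosity_of(genotypes, pedigree$father_id, varA)
  fzB <- zygosity_of(genotypes, pedigree$father_id, varB)
  mzA <- zygosity_of(genotypes, pedigree$mother_id, varA)
  mzB <- zygosity_of(genotypes, pedigree$mother_id, varB)

  origin_from_carriers <- function(zf, zm) {
    cf <- carries(zf); cm <- carries(zm)
    if (isTRUE(cf) && !isTRUE(cm)) "father"
    else if (isTRUE(cm) && !isTRUE(cf)) "mother"
    else "unknown"
  }

  unresolved <- function() {
    list(phase_status = "presumed_unconfirmed",
         parental_origin = stats::setNames(
           c(origin_from_carriers(fzA, mzA), origin_from_carriers(fzB, mzB)),
           c(varA, varB)))
  }

  father_typed <- !is.na(fzA) && !is.na(fzB)
  mother_typed <- !is.na(mzA) && !is.na(mzB)
  if (!father_typed || !mother_typed) return(unresolved())

  fd <- parent_diplotypes(fzA, fzB)
  md <- parent_diplotypes(mzA, mzB)
  configs <- list()
  for (f in fd) for (m in md) {
    for (fi in seq_len(nrow(f))) for (mi in seq_len(nrow(m))) {
      fh <- f[fi, ]; mh <- m[mi, ]
      if (fh[1] + mh[1] == 1L && fh[2] + mh[2] == 1L) {
        configs[[length(configs) + 1L]] <- c(
          cis = (fh[1] == 1L && fh[2] == 1L) || (mh[1] == 1L && mh[2] == 1L),
          a_from_father = fh[1] == 1L,
          b_from_father = fh[2] == 1L
        )
      }
    }
  }

  if (length(configs) == 0) {
    # no Mendelian transmission explains the pair: alleles absent from both
    # typed parents are de novo
    out <- unresolved()
    if (!carries(fzA) && !carries(mzA)) out$parental_origin[varA] <- "de_novo"
    if (!carries(fzB) && !carries(mzB)) out$parental_origin[varB] <- "de_novo"
    return(out)
  }

  cfg <- do.call(rbind, configs)
  status <- if (all(cfg[, "cis"])) "cis_rejected"
            else if (!any(cfg[, "cis"])) "confirmed_trans"
            else "presumed_unconfirmed"
  origin_of <- function(col) {
    if (all(cfg[, col])) "father" else if (!any(cfg[, col])) "mother" else "unknown"
  }
  list(phase_status = status,
       parental_origin = stats::setNames(
         c(origin_of("a_from_father"), origin_of("b_from_father")),
         c(varA, varB)))
}

#' Is a variant de novo in the proband?
#'
#' True only when trio data exist: proband heterozygous and both typed
#' parents homozygous reference. Without both parents the answer is FALSE
#' with reason "trio unavailable" — a singleton het can never be promoted to
#' de novo.
#'
#' @param vid variant id
#' @param genotypes genotype table
#' @param pedigree one pedigree row
#' @return list with `is_de_novo` (logical) and `reason` (character or NA)
#' @export
detect_de_novo <- function(vid, genotypes, pedigree) {
  if (is.na(pedigree$father_id) || is.na(pedigree$mother_id)) {
    return(list(is_de_novo = FALSE, reason = "trio unavailable"))
  }
  pz <- zygosity_of(genotypes, pedigree$proband_id, vid)
  fz <- zygosity_of(genotypes, pedigree$father_id, vid)
  mz <- zygosity_of(genotypes, pedigree$mother_id, vid)
  if (is.na(fz) || is.na(mz)) {
    return(list(is_de_novo = FALSE, reason = "parental genotype missing"))
  }
  ok <- identical(pz, "het") && fz == "hom_ref" && mz == "hom_ref"
  list(is_de_novo = ok, reason = if (ok) NA_character_ else "inherited or not het")
}

#' Is a variant a hemizygous X call in an affected male?
#'
#' @param variant one-row variant table (needs chrom, pos, variant_id)
#' @param genotypes genotype table
#' @param pedigree one pedigree row
#' @return logical
#' @export
detect_hemizygous <- function(variant, genotypes, pedigree) {
  if (!identical(pedigree$proband_sex, "male")) return(FALSE)
  if (!is_x_nonpar(variant$chrom, variant$pos)) return(FALSE)
  identical(zygosity_of(genotypes, pedigree$proband_id, variant$variant_id),
            "hemizygous")
}

#' Does a heterozygous dominant-gene variant segregate with affected status?
#'
#' For a proband-heterozygous variant in an AD-mode gene: any typed
#' unaffected family member carrying the allele makes it `non_segregating`;
#' a proband-only allele with both parents typed non-carriers `segregates`
#' (the de novo situation); untyped parents leave it `indeterminate`, which
#' is never counted as diagnostic.
#'
#' @param vid variant id
#' @param genotypes genotype table
#' @param pedigree one pedigree row (parents are unaffected in this simplex
#'   design)
#' @return one of "segregates", "non_segregating", "indeterminate"
#' @export
check_ad_segregation <- function(vid, genotypes, pedigree) {
  fz <- zygosity_of(genotypes, pedigree$father_id, vid)
  mz <- zygosity_of(genotypes, pedigree$mother_id, vid)
  if (isTRUE(carries(fz)) || isTRUE(carries(mz))) return("non_segregating")
  father_clear <- !is.na(pedigree$father_id) && !is.na(fz) && !carries(fz)
  mother_clear <- !is.na(pedigree$mother_id) && !is.na(mz) && !carries(mz)
  if (father_clear && mother_clear) return("segregates")
  "indeterminate"
}

mechanism_call <- function(subject_id, gene, mechanism, phase_status,
                           var1, var2 = NA_character_,
                           origin1 = NA_character_, origin2 = NA_character_,
                           note = NA_character_) {
  tibble(subject_id = subject_id, gene = gene, mechanism = mechanism,
         phase_status = phase_status, var1 = var1, var2 = var2,
         origin1 = origin1, origin2 = origin2, note = note)
}

empty_mechanisms <- function() {
  mechanism_call(character(0), character(0), character(0), character(0),
                 character(0), character(0), character(0), character(0),
                 character(0))
}

#' Detect bi-allelic genotypes in one gene
#'
#' Homozygous-alternate calls each yield a `homozygous` mechanism. When the
#' proband is heterozygous at two or more loci in the gene, every unordered
#' pair is phased with [resolve_phase()] and the best pair is kept
#' (`confirmed_trans` beats `presumed_unconfirmed` beats `cis_rejected`;
#' ties resolved by the variant ranking key, then lexicographic ids). A
#' `cis_rejected` pair is still reported so the caller can show why the gene
#' was not diagnostic, but it is never counted as a diagnosis.
#'
#' @param gene_variants variant table restricted to one gene
#' @param genotypes genotype table
#' @param pedigree one pedigree row
#' @param thresholds threshold set (used only for ranking tie-breaks)
#' @return tibble of mechanism calls (possibly empty)
#' @export
detect_biallelic <- function(gene_variants, genotypes, pedigree,
                             thresholds = default_thresholds()) {
  if (nrow(gene_variants) == 0) return(empty_mechanisms())
  if (length(unique(gene_variants$gene)) > 1) {
    abort("detect_biallelic expects variants from a single gene")
  }
  pid <- pedigree$proband_id
  zyg <- vapply(gene_variants$variant_id, function(v)
    zygosity_of(genotypes, pid, v) %||% NA_character_, character(1))
  calls <- empty_mechanisms()

  hom <- gene_variants$variant_id[!is.na(zyg) & zyg == "hom_alt"]
  for (v in hom) {
    calls <- bind_rows(calls, mechanism_call(
      pid, gene_variants$gene[1], "homozygous", "not_applicable", v))
  }

  hets <- gene_variants$variant_id[!is.na(zyg) & zyg == "het"]
  if (length(hets) >= 2) {
    # rank hets once so pair tie-breaks are deterministic
    hv <- gene_variants[match(hets, gene_variants$variant_id), ]
    hets <- hets[rank_key_order(hv, thresholds)]
    pairs <- utils::combn(hets, 2, simplify = FALSE)
    phased <- lapply(pairs, function(p)
      resolve_phase(p[1], p[2], genotypes, pedigree))
    score <- vapply(phased, function(x)
      match(x$phase_status,
            c("confirmed_trans", "presumed_unconfirmed", "cis_rejected")),
      integer(1))
    best <- which.min(score)  # pairs are already in rank order: first wins ties
    p <- pairs[[best]]; ph <- phased[[best]]
    calls <- bind_rows(calls, mechanism_call(
      pid, gene_variants$gene[1], "compound_het", ph$phase_status,
      p[1], p[2], ph$parental_origin[[p[1]]], ph$parental_origin[[p[2]]]))
  }
  calls
}

#' Score a mechanism call as diagnostic for a panel gene
#'
#' Encodes which genotype mechanisms count as a molecular diagnosis given
#' the gene's inheritance mode(s): homozygous or (non-cis) compound
#' heterozygous genotypes in AR genes, hemizygous genotypes in XL genes, and
#' de novo heterozygous genotypes in AD genes that segregate (any
#' non-segregating or indeterminate dominant singleton is excluded).
#'
#' @param mech one mechanism-call row
#' @param modes inheritance modes of the gene
#' @param segregation AD segregation status (only consulted for de novo)
#' @return logical
#' @export
is_diagnostic_mechanism <- function(mech, modes, segregation = "indeterminate") {
  if (mech$mechanism %in% c("homozygous", "compound_het")) {
    return("AR" %in% modes && !identical(mech$phase_status, "cis_rejected"))
  }
  if (mech$mechanism == "hemizygous") return("XL" %in% modes)
  if (mech$mechanism == "de_novo") {
    return("AD" %in% modes && identical(segregation, "segregates"))
  }
  FALSE
}
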